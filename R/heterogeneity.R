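#' Normalize each cell's expression vector to a z-score
#'
#' Centers each cell over the selected genes and scales to unit norm, so the
#' squared Euclidean distance between two normalized cells is exactly
#' `2 - 2 * rho`, where `rho` is the Pearson correlation of the two raw
#' expression vectors. (Scaling to unit norm rather than unit sample variance
#' only changes a constant factor shared by all cells; it is the convention
#' under which the distance-correlation identity is exact.)
#'
#' @param m an `ExpressionMatrix` (imputed: no missing entries).
#' @param genes optional gene subset.
#' @return a gene x cell matrix of normalized cell vectors.
#' @export
zscore_cells <- function(m, genes = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- if (is.null(genes)) m$values else subset_matrix(m, genes = genes)$values
  if (nrow(v) < 2) stop("need >= 2 genes to normalize cell vectors")
  centered <- sweep(v, 2, colMeans(v))
  norms <- sqrt(colSums(centered^2))
  if (any(norms == 0))
    stop("constant expression vector for cell(s): ",
         paste(utils::head(colnames(v)[norms == 0], 5), collapse = ", "))
  sweep(centered, 2, norms, "/")
}

#' Silhouette values of cells with tumors as clusters
#'
#' For cell i, `a(i)` is the average distance to the cells of its own tumor
#' and `b(i)` the minimum over other tumors of the average distance to that
#' tumor's cells; `s(i) = (b(i) - a(i)) / max(a(i), b(i))`. By default the
#' own-tumor average includes the zero self-distance (denominator = tumor
#' size); set `include_self = FALSE` for the conventional silhouette that
#' divides by size - 1.
#'
#' @param vectors gene x cell matrix of normalized cell vectors
#'   (from [zscore_cells()]).
#' @param tumor_of named character vector of tumor labels per cell.
#' @param include_self logical; see Details.
#' @return named numeric vector of silhouette values in `[-1, 1]`.
#' @export
silhouette_values <- function(vectors, tumor_of, include_self = TRUE) {
  cells <- colnames(vectors)
  tumor_of <- tumor_of[cells]
  tumors <- unique(tumor_of)
  if (length(tumors) < 2) stop("silhouette values need >= 2 tumors")
  # unit-norm columns: squared distance = 2 - 2 * crossprod
  G <- crossprod(vectors)
  D <- sqrt(pmax(2 - 2 * G, 0))
  n <- length(cells)
  sums <- sapply(tumors, function(t) rowSums(D[, tumor_of == t, drop = FALSE]))
  sizes <- table(tumor_of)[tumors]
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- tumor_of[i]
    a <- if (include_self) sums[i, own] / sizes[own]
         else {
           if (sizes[own] == 1) 0 else sums[i, own] / (sizes[own] - 1)
         }
    other <- setdiff(tumors, own)
    b <- min(sums[i, other] / sizes[other])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  stats::setNames(s, cells)
}

#' Per-tumor fractions of cells with negative silhouette values
#'
#' @param silhouettes named vector from [silhouette_values()].
#' @param tumor_of named tumor labels covering all cells in `silhouettes`.
#' @return list with `per_tumor` (named fractions) and `avg_nsv` (their
#'   unweighted mean).
#' @export
nsv_fractions <- function(silhouettes, tumor_of) {
  cells <- names(silhouettes)
  if (any(!cells %in% names(tumor_of)))
    stop("tumor labels must cover all cells")
  lab <- tumor_of[cells]
  per <- tapply(silhouettes < 0, lab, mean)
  per <- stats::setNames(as.numeric(per), names(per))
  list(per_tumor = per, avg_nsv = mean(per))
}

#' Intra- and inter-tumoral correlation coefficients
#'
#' Pearson correlations of raw expression between all unordered cell pairs,
#' split into same-tumor (intra) and cross-tumor (inter) groups. The two group
#' sizes sum to `choose(n_cells, 2)`.
#'
#' @param m an `ExpressionMatrix` (imputed).
#' @param genes optional gene subset (>= 2 genes).
#' @param cells optional cell subset.
#' @return list with numeric vectors `intra` and `inter`.
#' @export
intra_inter_correlations <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  sub <- subset_matrix(m, genes = genes, cells = cells)
  if (ncol(sub$values) < 2) stop("need >= 2 cells")
  if (nrow(sub$values) < 2) stop("need >= 2 genes to correlate cells")
  C <- stats::cor(sub$values)
  same <- outer(sub$tumor_of, sub$tumor_of, "==")
  ut <- upper.tri(C)
  list(intra = C[ut & same], inter = C[ut & !same])
}

# Rejection sampling from a Gaussian-KDE density estimate truncated to
# [lower, upper]: draw x ~ U(domain), accept when U(0, p_max) <= p(x).
rejection_sample <- function(values, n, lower = -1, upper = 1, grid_n = 1001) {
  if (length(values) < 2) stop("need >= 2 values to estimate a density")
  d <- stats::density(values, from = lower, to = upper, n = grid_n)
  p_max <- max(d$y)
  if (p_max <= 0) stop("degenerate density estimate")
  out <- numeric(0)
  while (length(out) < n) {
    draw <- max(2L * n, 1000L)
    x <- stats::runif(draw, lower, upper)
    p <- stats::approx(d$x, d$y, xout = x)$y
    q <- stats::runif(draw, 0, p_max)
    out <- c(out, x[q <= p])
  }
  out[seq_len(n)]
}

#' The p_diff deviation score between two correlation distributions
#'
#' Estimates `P(X > Y + eps) - P(X < Y - eps)` where `X` is drawn from the
#' intra-tumoral and `Y` from the inter-tumoral correlation-coefficient
#' distribution. Densities are estimated by Gaussian kernel density estimation
#' (Silverman bandwidth) on `[-1, 1]`, `n_samples` values are drawn from each
#' by rejection sampling, and the two probabilities are the fractions of
#' matched sample pairs satisfying each relation. Positive values indicate
#' intra-tumoral homogeneity.
#'
#' @param intra,inter nonempty numeric vectors of correlation coefficients.
#' @param epsilon non-negative margin (default 0.05).
#' @param n_samples number of rejection samples per distribution
#'   (default 1e5).
#' @param seed optional integer seed for reproducibility.
#' @return a single number in `[-1, 1]`.
#' @export
p_diff <- function(intra, inter, epsilon = 0.05, n_samples = 1e5, seed = NULL) {
  if (!length(intra) || !length(inter)) stop("both samples must be nonempty")
  if (epsilon < 0) stop("`epsilon` must be >= 0")
  if (n_samples <= 0) stop("`n_samples` must be positive")
  if (!is.null(seed)) set.seed(seed)
  X <- rejection_sample(intra, n_samples)
  Y <- rejection_sample(inter, n_samples)
  mean(X > Y + epsilon) - mean(X < Y - epsilon)
}

#' Per-tumor transcriptome entropy under a gene-independence assumption
#'
#' Within each tumor the marginal density of each gene is estimated by
#' Gaussian kernel density estimation (Silverman bandwidth), its differential
#' entropy computed by numerical integration of `-p log p`, and the per-tumor
#' entropy is the sum over genes. Reported in bits by default.
#'
#' @param m an `ExpressionMatrix` (imputed).
#' @param genes optional gene subset.
#' @param base logarithm base (2 = bits, `exp(1)` = nats).
#' @return named numeric vector of per-tumor entropies.
#' @export
entropy_per_tumor <- function(m, genes = NULL, base = 2) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  sub <- subset_matrix(m, genes = genes)
  tumors <- unique(sub$tumor_of)
  ent <- sapply(tumors, function(t) {
    v <- sub$values[, sub$tumor_of == t, drop = FALSE]
    if (ncol(v) < 2) stop("entropy needs >= 2 cells in tumor ", t)
    per_gene <- apply(v, 1, function(x) {
      if (stats::sd(x) == 0) {
        warning("skipping zero-variance gene within tumor ", t)
        return(NA_real_)
      }
      d <- stats::density(x)
      dx <- d$x[2] - d$x[1]
      y <- d$y[d$y > 0]
      -sum(y * log(y, base = base)) * dx
    })
    sum(per_gene, na.rm = TRUE)
  })
  stats::setNames(ent, tumors)
}

#' Full intra-tumoral heterogeneity report
#'
#' Bundles the average NSV fraction, the p_diff score and (optionally) the
#' entropy baseline for a matrix, a gene subset and a cell subset (e.g. cancer
#' cells only).
#'
#' @param m an `ExpressionMatrix` (imputed).
#' @param genes optional gene subset.
#' @param cells optional cell subset.
#' @param epsilon p_diff margin (default 0.05).
#' @param n_samples rejection-sample count (default 1e5).
#' @param seed optional integer seed (recorded in the report).
#' @param entropy also compute per-tumor entropies (default FALSE).
#' @param include_self silhouette convention, see [silhouette_values()].
#' @return an object of class `HeterogeneityReport`: list with
#'   `nsv_per_tumor`, `avg_nsv`, `p_diff`, `epsilon`, `n_samples`, `seed`,
#'   `entropy_per_tumor`, `avg_entropy`, `gene_subset`.
#' @export
heterogeneity_report <- function(m, genes = NULL, cells = NULL,
                                 epsilon = 0.05, n_samples = 1e5, seed = NULL,
                                 entropy = FALSE, include_self = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  sub <- subset_matrix(m, genes = genes, cells = cells)
  z <- zscore_cells(sub)
  sil <- silhouette_values(z, sub$tumor_of, include_self = include_self)
  nsv <- nsv_fractions(sil, sub$tumor_of)
  cc <- intra_inter_correlations(sub)
  pd <- p_diff(cc$intra, cc$inter, epsilon = epsilon,
               n_samples = n_samples, seed = seed)
  ent <- if (entropy) entropy_per_tumor(sub) else NULL
  structure(list(nsv_per_tumor = nsv$per_tumor, avg_nsv = nsv$avg_nsv,
                 p_diff = pd, epsilon = epsilon, n_samples = n_samples,
                 seed = seed, entropy_per_tumor = ent,
                 avg_entropy = if (entropy) mean(ent) else NULL,
                 gene_subset = genes),
            class = "HeterogeneityReport")
}

#' @exportS3Method base::print
print.HeterogeneityReport <- function(x, ...) {
  cat(sprintf("HeterogeneityReport: avg NSV %.4f, p_diff %.4f (eps %.2f)\n",
              x$avg_nsv, x$p_diff, x$epsilon))
  if (!is.null(x$avg_entropy))
    cat(sprintf("  avg entropy %.3f bits\n", x$avg_entropy))
  invisible(x)
}
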