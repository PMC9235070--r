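#' Expression-coherence p_diff of a gene cluster in bulk data
#'
#' Compares the distribution of pairwise Pearson correlations among the
#' cluster's member genes with a background distribution of pairwise
#' correlations among `background_n` randomly selected genes, via the
#' [p_diff()] deviation score. Positive values indicate stronger coherence
#' than background.
#'
#' @param genes member gene identifiers.
#' @param bulk a fully observed `ExpressionMatrix` (genes x samples).
#' @param background_n background sample size (default 8000; all genes when
#'   fewer exist).
#' @param epsilon,n_samples,seed passed to [p_diff()].
#' @return the p_diff score, or `NA` (with a warning) when fewer than two
#'   member genes map into the matrix.
#' @export
coherence_pdiff <- function(genes, bulk, background_n = 8000,
                            epsilon = 0.05, n_samples = 1e5, seed = NULL) {
  stopifnot(inherits(bulk, "ExpressionMatrix"))
  if (!is.null(seed)) set.seed(seed)
  genes <- intersect(genes, rownames(bulk$values))
  if (length(genes) < 2) {
    warning("fewer than 2 cluster genes present in the bulk matrix")
    return(NA_real_)
  }
  bg <- rownames(bulk$values)
  if (length(bg) > background_n) bg <- sample(bg, background_n)
  pair_cors <- function(gs) {
    C <- stats::cor(t(bulk$values[gs, , drop = FALSE]))
    C[upper.tri(C)]
  }
  p_diff(pair_cors(genes), pair_cors(bg), epsilon = epsilon,
         n_samples = n_samples)
}

#' Per-gene univariate Cox regression coefficients
#'
#' Fits, for each gene, a univariate proportional-hazards model of the
#' survival/censoring times on that gene's expression (Breslow tie handling).
#' Positive coefficients mean higher expression associates with shorter
#' survival.
#'
#' @param bulk a fully observed `ExpressionMatrix`.
#' @param surv a `SurvivalTable` covering the bulk samples.
#' @param genes optional gene subset (default all).
#' @return named numeric vector of coefficients (non-converging fits dropped
#'   with a message of their count).
#' @export
cox_coefficients <- function(bulk, surv, genes = NULL) {
  stopifnot(inherits(bulk, "ExpressionMatrix"))
  samples <- intersect(colnames(bulk$values), surv$sample)
  if (length(samples) < 3) stop("survival table must cover the bulk samples")
  surv <- surv[match(samples, surv$sample), ]
  y <- survival::Surv(surv$time, surv$event)
  if (is.null(genes)) genes <- rownames(bulk$values)
  coefs <- rep(NA_real_, length(genes))
  names(coefs) <- genes
  for (g in genes) {
    x <- bulk$values[g, samples]
    if (stats::sd(x) == 0) next
    fit <- tryCatch(
      survival::coxph(y ~ x, ties = "breslow"),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) coefs[g] <- unname(stats::coef(fit)[1])
  }
  dropped <- sum(is.na(coefs))
  if (dropped) message(dropped, " gene fit(s) skipped (non-converging or constant)")
  coefs[!is.na(coefs)]
}

#' Survival-association p_diff of a gene cluster in bulk data
#'
#' Compares the distribution of the cluster genes' univariate Cox regression
#' coefficients with the background distribution over all genes, via
#' [p_diff()]. A positive deviation means the cluster's expression is
#' negatively associated with survival times (coefficients shifted upward).
#'
#' @param genes member gene identifiers.
#' @param bulk a fully observed `ExpressionMatrix` (conventionally
#'   CDF-transformed, see [cdf_transform()]).
#' @param surv a `SurvivalTable`.
#' @param epsilon,n_samples,seed passed to [p_diff()].
#' @param coefs optional precomputed [cox_coefficients()] for all genes
#'   (avoids refitting when scoring many clusters).
#' @return the p_diff score, or `NA` when fewer than two member genes have
#'   coefficients.
#' @export
cox_pdiff <- function(genes, bulk, surv, epsilon = 0.05, n_samples = 1e5,
                      seed = NULL, coefs = NULL) {
  if (is.null(coefs)) coefs <- cox_coefficients(bulk, surv)
  if (!is.null(seed)) set.seed(seed)
  member <- coefs[intersect(genes, names(coefs))]
  if (length(member) < 2) {
    warning("fewer than 2 cluster genes with Cox coefficients")
    return(NA_real_)
  }
  # coefficients are unbounded; p_diff domain follows the pooled range
  rng <- range(coefs)
  pad <- 0.05 * diff(rng)
  p_diff_on(member, coefs, lower = rng[1] - pad, upper = rng[2] + pad,
            epsilon = epsilon, n_samples = n_samples)
}

# p_diff on an arbitrary bounded domain (correlations use [-1, 1])
p_diff_on <- function(x, y, lower, upper, epsilon = 0.05, n_samples = 1e5) {
  X <- rejection_sample(x, n_samples, lower = lower, upper = upper)
  Y <- rejection_sample(y, n_samples, lower = lower, upper = upper)
  mean(X > Y + epsilon) - mean(X < Y - epsilon)
}

#' Random-walk enrichment of meta-cluster members among top-ranked clusters
#'
#' Scans the clusters sorted by a score (e.g. coherence or Cox p_diff,
#' descending), incrementing a walk at each member of the meta cluster. The
#' normalized walk `C1(x)` is compared with the straight line `C0(x)` joining
#' its endpoints by a one-sided Kolmogorov-Smirnov test for positive deviation
#' (members enriched at the top of the list).
#'
#' @param members character vector of member cluster ids.
#' @param sorted_clusters all cluster ids, sorted by descending score.
#' @return list with `statistic` (max positive deviation) and `p_value`
#'   (one-sided asymptotic `exp(-2 n D^2)` over the n-point curves).
#' @export
rank_enrichment <- function(members, sorted_clusters) {
  if (!length(members)) stop("meta cluster has no members")
  if (!all(members %in% sorted_clusters))
    stop("sorted list must cover all member clusters")
  n <- length(sorted_clusters)
  walk <- cumsum(sorted_clusters %in% members)
  total <- walk[n]
  C1 <- walk / total
  C0 <- seq_len(n) / n
  D <- max(C1 - C0)
  p <- exp(-2 * n * max(D, 0)^2)
  list(statistic = D, p_value = min(1, p))
}

#' Validate meta gene clusters in bulk expression and survival data
#'
#' For every reduced gene cluster of a dataset, computes the expression
#' coherence p_diff and the survival-association (Cox) p_diff in the bulk
#' data; then, for every meta gene cluster, tests whether its member clusters
#' are enriched among the top-ranked clusters of each metric.
#'
#' @param hier the dataset's `ReducedHierarchy`.
#' @param assignment a `MetaClusterAssignment`.
#' @param dataset this dataset's index in the assignment.
#' @param bulk fully observed bulk `ExpressionMatrix`.
#' @param surv a `SurvivalTable`.
#' @param background_n,epsilon,n_samples,seed see [coherence_pdiff()].
#' @return an object of class `ValidationResult`: list with `coherence_pdiff`,
#'   `cox_pdiff` (named per cluster) and `enrichment_p` (data.frame meta x
#'   metric).
#' @export
validate_bulk <- function(hier, assignment, dataset, bulk, surv,
                          background_n = 8000, epsilon = 0.05,
                          n_samples = 1e5, seed = NULL) {
  g <- if (inherits(hier, "ReducedHierarchy")) hier$graph else hier
  if (!is.null(seed)) set.seed(seed)
  ids <- as.character(g$nodes$id)
  coefs <- cox_coefficients(bulk, surv)
  coh <- stats::setNames(rep(NA_real_, length(ids)), ids)
  cox <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (id in ids) {
    genes <- g$members[[id]]
    coh[id] <- suppressWarnings(
      coherence_pdiff(genes, bulk, background_n = background_n,
                      epsilon = epsilon, n_samples = n_samples))
    cox[id] <- suppressWarnings(
      cox_pdiff(genes, bulk, surv, epsilon = epsilon, n_samples = n_samples,
                coefs = coefs))
  }
  pref <- paste0(dataset, ":")
  rows <- list()
  for (k in seq_along(assignment$metas)) {
    keys <- names(assignment$assignments)[vapply(assignment$assignments,
                                                 function(v) k %in% v,
                                                 logical(1))]
    members <- sub("^[0-9]+:", "", keys[startsWith(keys, pref)])
    members <- intersect(members, ids)
    if (!length(members)) next
    for (metric in c("coherence", "cox")) {
      v <- if (metric == "coherence") coh else cox
      ok <- names(v)[!is.na(v)]
      sorted <- ok[order(-v[ok])]
      mem <- intersect(members, ok)
      if (!length(mem)) next
      re <- rank_enrichment(mem, sorted)
      rows[[length(rows) + 1L]] <- data.frame(meta = k, metric = metric,
                                              statistic = re$statistic,
                                              p_value = re$p_value)
    }
  }
  structure(list(coherence_pdiff = coh, cox_pdiff = cox,
                 enrichment_p = if (length(rows)) do.call(rbind, rows)
                 else data.frame(meta = integer(), metric = character(),
                                 statistic = numeric(), p_value = numeric()),
                 background_spec = sprintf("%d randomly selected genes",
                                           min(background_n,
                                               nrow(bulk$values)))),
            class = "ValidationResult")
}
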