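#' Remove genes with too many missing entries
#'
#' Drops every gene whose fraction of missing (dropout) entries over all cells
#' is strictly greater than `max_missing_frac`; a gene at exactly the threshold
#' is kept. The cell set is unchanged.
#'
#' @param m an `ExpressionMatrix`.
#' @param max_missing_frac maximum tolerated missing fraction, in `[0, 1]`
#'   (default 0.7).
#' @return the filtered `ExpressionMatrix` (possibly with zero genes).
#' @export
filter_sparse_genes <- function(m, max_missing_frac = 0.7) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (max_missing_frac < 0 || max_missing_frac > 1)
    stop("`max_missing_frac` must be in [0, 1]")
  missing_frac <- 1 - rowMeans(m$observed)
  keep <- rownames(m$values)[missing_frac <= max_missing_frac]
  subset_matrix(m, genes = keep)
}

#' Impute dropout entries
#'
#' `"mean"` replaces each missing entry with the mean expression over the
#' observed entries of the same gene; `"zero"` replaces missing entries with
#' zeros. Observed entries are never modified.
#'
#' @param m an `ExpressionMatrix`.
#' @param strategy `"mean"` or `"zero"`.
#' @return an `ExpressionMatrix` with all entries observed.
#' @export
impute <- function(m, strategy = c("mean", "zero")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  strategy <- match.arg(strategy)
  values <- m$values
  if (strategy == "mean") {
    n_obs <- rowSums(m$observed)
    if (any(n_obs == 0))
      stop("mean imputation undefined for all-missing gene(s): ",
           paste(utils::head(rownames(values)[n_obs == 0], 5), collapse = ", "))
    vo <- values
    vo[!m$observed] <- 0
    row_means <- rowSums(vo) / n_obs
    fill <- matrix(row_means, nrow(values), ncol(values))
    values[!m$observed] <- fill[!m$observed]
  } else {
    values[!m$observed] <- 0
  }
  expression_matrix(values, tumor = m$tumor_of,
                    observed = matrix(TRUE, nrow(values), ncol(values)),
                    cell_type = m$cell_type_of, population = m$population)
}

#' Transform each gene to its empirical CDF values
#'
#' Replaces each gene's values by their empirical cumulative distribution
#' function values over samples: rank / n with ties averaged, so outputs lie in
#' (0, 1] and the largest observed value maps to 1. Intended for fully observed
#' bulk data.
#'
#' @param m an `ExpressionMatrix` with no missing entries.
#' @return the transformed `ExpressionMatrix`.
#' @export
cdf_transform <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!all(m$observed))
    stop("cdf_transform requires a fully observed matrix; impute first")
  n <- ncol(m$values)
  values <- t(apply(m$values, 1, function(x) rank(x, ties.method = "average") / n))
  dimnames(values) <- dimnames(m$values)
  expression_matrix(values, tumor = m$tumor_of, observed = m$observed,
                    cell_type = m$cell_type_of, population = m$population)
}
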