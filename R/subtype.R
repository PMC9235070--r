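#' Extend a marker panel with co-expressed companion genes
#'
#' Subdivides the panel into `n_groups` by consensus k-means on the first bulk
#' dataset, computes each non-panel gene's correlations with the panel genes
#' in both bulk datasets, averages them within each panel group, ranks genes
#' by the maximum group-level average correlation in each dataset separately,
#' and returns the genes appearing in both datasets' top `top_n` lists.
#'
#' @param panel character vector of marker genes (e.g. PAM50).
#' @param bulk_a,bulk_b two fully observed bulk `ExpressionMatrix` objects.
#' @param n_groups panel subdivisions (default 3).
#' @param top_n per-dataset shortlist size (default 200).
#' @param n_runs consensus k-means runs (default 50).
#' @param seed optional integer seed.
#' @return list with `extended` (panel plus companions), `companions`, and
#'   `groups` (named panel-group assignment).
#' @export
extend_panel <- function(panel, bulk_a, bulk_b, n_groups = 3, top_n = 200,
                         n_runs = 50, seed = NULL) {
  stopifnot(inherits(bulk_a, "ExpressionMatrix"),
            inherits(bulk_b, "ExpressionMatrix"))
  if (!is.null(seed)) set.seed(seed)
  present <- intersect(panel, intersect(rownames(bulk_a$values),
                                        rownames(bulk_b$values)))
  dropped <- setdiff(panel, present)
  if (length(dropped))
    warning("panel gene(s) absent from a matrix: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  if (length(present) < n_groups) stop("too few panel genes present")
  groups <- consensus_kmeans(bulk_a$values[present, , drop = FALSE],
                             k = n_groups, n_runs = n_runs)$assignment
  rank_in <- function(bulk) {
    others <- setdiff(rownames(bulk$values), panel)
    C <- stats::cor(t(bulk$values[others, , drop = FALSE]),
                    t(bulk$values[present, , drop = FALSE]))
    grp_avg <- sapply(seq_len(n_groups), function(g)
      rowMeans(C[, names(groups)[groups == g], drop = FALSE]))
    best <- apply(grp_avg, 1, max)
    names(sort(best, decreasing = TRUE))[seq_len(min(top_n, length(best)))]
  }
  companions <- intersect(rank_in(bulk_a), rank_in(bulk_b))
  list(extended = c(present, companions), companions = companions,
       groups = groups)
}

#' Predict the subtype of each cell by correlation to bulk references
#'
#' Computes pairwise-complete Pearson correlations between each cell and every
#' reference sample over the panel genes, averages over the reference samples
#' of each subtype, and assigns the cell to the subtype with maximum average
#' correlation. The full average-correlation vector is retained so cells can
#' later be filtered by a minimum correlation threshold.
#'
#' @param m single-cell `ExpressionMatrix` (dropouts allowed; correlations use
#'   observed entries only).
#' @param ref fully observed reference `ExpressionMatrix` (bulk samples).
#' @param ref_subtype named character vector: reference sample -> subtype.
#' @param panel panel genes used for the correlations.
#' @param min_genes minimum shared observed panel genes per cell-reference
#'   pair (default 3); cells with no valid comparisons are unclassified.
#' @return data.frame with `cell`, `subtype` (NA = unclassified), `max_corr`,
#'   and one `avg_corr_<subtype>` column per subtype.
#' @export
predict_cell_subtype <- function(m, ref, ref_subtype, panel, min_genes = 3) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(ref, "ExpressionMatrix"))
  genes <- intersect(panel, intersect(rownames(m$values),
                                      rownames(ref$values)))
  if (length(genes) < min_genes) stop("too few shared panel genes")
  subtypes <- sort(unique(ref_subtype))
  sc <- m$values[genes, , drop = FALSE]
  sc[!m$observed[genes, , drop = FALSE]] <- NA
  rv <- ref$values[genes, colnames(ref$values), drop = FALSE]
  C <- suppressWarnings(stats::cor(sc, rv, use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(sc) * 1, matrix(1, length(genes), ncol(rv)))
  C[shared < min_genes] <- NA
  avg <- do.call(cbind, lapply(subtypes, function(s) {
    cols <- names(ref_subtype)[ref_subtype == s]
    rowMeans(C[, cols, drop = FALSE], na.rm = TRUE)
  }))
  colnames(avg) <- subtypes
  avg[is.nan(avg)] <- NA
  call <- apply(avg, 1, function(r)
    if (all(is.na(r))) NA_character_ else subtypes[which.max(r)])
  out <- data.frame(cell = colnames(m$values), subtype = call,
                    max_corr = apply(avg, 1, function(r)
                      if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (s in subtypes) out[[paste0("avg_corr_", s)]] <- avg[, s]
  out
}

#' Predict each patient's subtype from its cells' predictions
#'
#' Assigns each tumor (patient) to the subtype with the most classified cells
#' (plurality vote). Ties are broken toward the subtype whose cells have the
#' higher mean average correlation and flagged as ambiguous. Cells below
#' `min_corr` or unclassified are excluded first.
#'
#' @param cell_calls data.frame from [predict_cell_subtype()].
#' @param tumor_of named tumor labels per cell.
#' @param min_corr minimum `max_corr` for a cell to count (default 0.1).
#' @return data.frame with `tumor`, `subtype`, `ambiguous`, `n_cells`, and one
#'   `frac_<subtype>` composition column per subtype (fractions over
#'   classified cells, summing to 1).
#' @export
predict_patient_subtype <- function(cell_calls, tumor_of, min_corr = 0.1) {
  keep <- !is.na(cell_calls$subtype) & !is.na(cell_calls$max_corr) &
    cell_calls$max_corr > min_corr
  calls <- cell_calls[keep, , drop = FALSE]
  calls$tumor <- tumor_of[calls$cell]
  subtypes <- sort(unique(calls$subtype))
  rows <- list()
  for (t in unique(tumor_of)) {
    sub <- calls[calls$tumor == t, , drop = FALSE]
    if (!nrow(sub)) next
    counts <- table(factor(sub$subtype, levels = subtypes))
    top <- names(counts)[counts == max(counts)]
    ambiguous <- length(top) > 1
    if (ambiguous) {
      mc <- vapply(top, function(s)
        mean(sub$max_corr[sub$subtype == s]), numeric(1))
      top <- top[which.max(mc)]
    }
    row <- data.frame(tumor = t, subtype = top, ambiguous = ambiguous,
                      n_cells = nrow(sub), stringsAsFactors = FALSE)
    for (s in subtypes) row[[paste0("frac_", s)]] <-
      as.numeric(counts[s]) / nrow(sub)
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no tumor has classified cells")
  do.call(rbind, rows)
}
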