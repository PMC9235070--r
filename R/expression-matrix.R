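#' Construct an expression matrix with dropout mask and tumor labels
#'
#' The universal input container of the package: a gene x cell matrix of
#' normalized expression values (RPKM/FPKM-like), a boolean mask of observed
#' (non-dropout) entries, and a cell-to-tumor (patient) label map. An optional
#' cell-type map distinguishes cancer cells from normal cell subtypes.
#'
#' @param values numeric gene x cell matrix with unique rownames (genes) and
#'   colnames (cells). `NA` entries are taken as missing unless `observed` is
#'   supplied. Zeros are observed values, not dropouts.
#' @param tumor character vector of tumor/patient labels, one per cell, named
#'   by cell or in column order.
#' @param observed logical matrix of the same dimension; `TRUE` marks a valid
#'   entry. Defaults to `!is.na(values)`.
#' @param cell_type optional character vector of cell-type labels per cell.
#' @param population optional per-cell ground-truth population labels
#'   (simulations only).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `observed`, `tumor_of`, `cell_type_of`, `population`.
#' @export
expression_matrix <- function(values, tumor, observed = NULL,
                              cell_type = NULL, population = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) && nrow(values) > 0)
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)) && ncol(values) > 0)
    colnames(values) <- paste0("c", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("gene identifiers must be unique")
  if (anyDuplicated(colnames(values)))
    stop("cell identifiers must be unique")
  if (is.null(observed)) {
    observed <- !is.na(values)
  } else {
    observed <- as.matrix(observed)
    if (!identical(dim(observed), dim(values)))
      stop("`values` and `observed` must have identical dimensions")
  }
  dimnames(observed) <- dimnames(values)
  align_cells <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (!is.null(names(x))) {
      miss <- setdiff(colnames(values), names(x))
      if (length(miss))
        stop("missing ", what, " label for cell(s): ",
             paste(utils::head(miss, 5), collapse = ", "))
      x <- x[colnames(values)]
    } else if (length(x) == ncol(values)) {
      names(x) <- colnames(values)
    } else {
      stop("`", what, "` must have one entry per cell")
    }
    as.character(stats::setNames(as.character(x), names(x)))
  }
  tumor_of <- stats::setNames(align_cells(tumor, "tumor"), colnames(values))
  structure(
    list(values = values, observed = observed, tumor_of = tumor_of,
         cell_type_of = if (is.null(cell_type)) NULL else
           stats::setNames(align_cells(cell_type, "cell_type"), colnames(values)),
         population = if (is.null(population)) NULL else
           stats::setNames(align_cells(population, "population"), colnames(values))),
    class = "ExpressionMatrix")
}

#' @exportS3Method base::print
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells, %d tumors, %.1f%% observed\n",
              nrow(x$values), ncol(x$values), length(unique(x$tumor_of)),
              100 * mean(x$observed)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Restrict an expression matrix to a subset of genes and/or cells
#'
#' @param m an `ExpressionMatrix`.
#' @param genes,cells character vectors of identifiers to keep (default all).
#' @return the restricted `ExpressionMatrix`.
#' @export
subset_matrix <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(genes)) genes <- rownames(m$values)
  if (is.null(cells)) cells <- colnames(m$values)
  bad <- setdiff(genes, rownames(m$values))
  if (length(bad)) stop("unknown gene(s): ", paste(utils::head(bad, 5), collapse = ", "))
  bad <- setdiff(cells, colnames(m$values))
  if (length(bad)) stop("unknown cell(s): ", paste(utils::head(bad, 5), collapse = ", "))
  expression_matrix(m$values[genes, cells, drop = FALSE],
                    tumor = m$tumor_of[cells],
                    observed = m$observed[genes, cells, drop = FALSE],
                    cell_type = if (!is.null(m$cell_type_of)) m$cell_type_of[cells],
                    population = if (!is.null(m$population)) m$population[cells])
}
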