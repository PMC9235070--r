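#' Read an expression matrix from delimited text or Matrix-Market files
#'
#' Delimited form: genes in rows, cells in columns, a header row of cell
#' identifiers, first column gene identifiers. Empty fields, `NA` and `NaN`
#' encode missing (dropout) entries; zeros are observed values. Matrix-Market
#' form: a sparse triplet file where stored entries are observed and absent
#' entries are missing, accompanied by one-gene-per-line and one-cell-per-line
#' identifier files.
#'
#' @param path path to the matrix file (`.tsv`/`.csv` or `.mtx`).
#' @param labels optional path to a cell-label table (see [read_cell_labels()]);
#'   otherwise `tumor` must be given.
#' @param tumor optional named character vector of tumor labels per cell.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; guessed from the extension.
#' @param genes_file,cells_file identifier files for the `mtx` format.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, labels = NULL, tumor = NULL,
                            format = c("auto", "tsv", "csv", "mtx"),
                            genes_file = NULL, cells_file = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", "tsv")
  }
  if (format == "mtx") {
    if (is.null(genes_file)) genes_file <- paste0(path, ".genes")
    if (is.null(cells_file)) cells_file <- paste0(path, ".cells")
    sm <- Matrix::readMM(path)
    genes <- readLines(genes_file)
    cells <- readLines(cells_file)
    if (nrow(sm) != length(genes) || ncol(sm) != length(cells))
      stop("matrix dimensions do not match the gene/cell identifier files")
    values <- matrix(NA_real_, length(genes), length(cells),
                     dimnames = list(genes, cells))
    tm <- as(sm, "TsparseMatrix")
    values[cbind(tm@i + 1L, tm@j + 1L)] <- tm@x
    observed <- matrix(FALSE, length(genes), length(cells))
    observed[cbind(tm@i + 1L, tm@j + 1L)] <- TRUE
  } else {
    sep <- if (format == "csv") "," else "\t"
    lines <- readLines(path)
    if (!length(lines)) stop("empty expression file: ", path)
    header <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
    cells <- header[-1]
    if (!length(cells)) stop("malformed header (no cell identifiers) at line 1")
    n <- length(lines) - 1L
    genes <- character(n)
    values <- matrix(NA_real_, n, length(cells))
    for (i in seq_len(n)) {
      fields <- strsplit(lines[[i + 1L]], sep, fixed = TRUE)[[1]]
      if (length(fields) != length(cells) + 1L)
        stop("line ", i + 1L, ": expected ", length(cells) + 1L,
             " fields, found ", length(fields))
      genes[i] <- fields[1]
      v <- fields[-1]
      miss <- v == "" | toupper(v) %in% c("NA", "NAN")
      num <- suppressWarnings(as.numeric(v))
      if (any(is.na(num) & !miss))
        stop("line ", i + 1L, ": non-numeric entry '",
             v[which(is.na(num) & !miss)[1]], "'")
      num[miss] <- NA_real_
      values[i, ] <- num
    }
    if (anyDuplicated(genes))
      stop("duplicate gene identifier(s): ",
           paste(utils::head(unique(genes[duplicated(genes)]), 5), collapse = ", "))
    dimnames(values) <- list(genes, cells)
    observed <- !is.na(values)
  }
  lab <- NULL; ct <- NULL
  if (!is.null(labels)) {
    tab <- read_cell_labels(labels)
    lab <- stats::setNames(tab$tumor, tab$cell)
    if (!is.null(tab$cell_type)) ct <- stats::setNames(tab$cell_type, tab$cell)
  } else if (!is.null(tumor)) {
    lab <- tumor
  } else {
    lab <- stats::setNames(rep("tumor1", ncol(values)), colnames(values))
  }
  expression_matrix(values, tumor = lab, observed = observed, cell_type = ct)
}

#' Write an expression matrix to delimited text or Matrix-Market files
#'
#' Inverse of [read_expression()]: `read_expression(write_expression(m))`
#' recovers values, mask and (with `labels`) tumor assignments.
#'
#' @param m an `ExpressionMatrix`.
#' @param path output path.
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @param labels optional path for the cell-label table.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, format = c("tsv", "csv", "mtx"),
                             labels = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  format <- match.arg(format)
  if (format == "mtx") {
    idx <- which(m$observed, arr.ind = TRUE)
    sm <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2],
                               x = m$values[idx],
                               dims = dim(m$values), repr = "T")
    Matrix::writeMM(sm, path)
    writeLines(rownames(m$values), paste0(path, ".genes"))
    writeLines(colnames(m$values), paste0(path, ".cells"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    v <- m$values
    v[!m$observed] <- NA
    out <- apply(v, 1, function(r) paste(ifelse(is.na(r), "NA", format(r, digits = 15)),
                                         collapse = sep))
    lines <- c(paste(c("gene", colnames(v)), collapse = sep),
               paste(rownames(v), out, sep = sep))
    writeLines(lines, path)
  }
  if (!is.null(labels)) {
    df <- data.frame(cell = colnames(m$values), tumor = unname(m$tumor_of))
    if (!is.null(m$cell_type_of)) df$cell_type <- unname(m$cell_type_of)
    utils::write.table(df, labels, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a cell-label table
#'
#' A delimited table with columns `cell`, `tumor` and optionally `cell_type`.
#'
#' @param path path to the TSV file.
#' @return a data.frame with columns `cell`, `tumor` and, when present,
#'   `cell_type`.
#' @export
read_cell_labels <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("cell", "tumor") %in% names(tab)))
    stop("label table must have 'cell' and 'tumor' columns")
  tab
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: tab-separated name, description, then member genes.
#'
#' @param path path to the `.gmt` file.
#' @param universe optional character vector of gene identifiers to use as the
#'   enrichment universe; defaults to the union of all set members.
#' @return an object of class `GeneSetCollection`: list with `sets` (named
#'   list of character vectors) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("line ", i, ": GMT lines need a name, a description and >= 1 member")
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("line ", i, ": empty gene set '", fields[1], "'")
    sets[[fields[1]]] <- members
  }
  gene_set_collection(sets, universe)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (each nonempty).
#' @param universe optional universe of gene identifiers; must contain every
#'   set member. Defaults to the union of the sets.
#' @return a `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (!length(sets) || is.null(names(sets)))
    stop("`sets` must be a nonempty named list")
  if (any(!lengths(sets))) stop("every gene set must be nonempty")
  all_members <- unique(unlist(sets, use.names = FALSE))
  if (is.null(universe)) universe <- all_members
  if (length(setdiff(all_members, universe)))
    stop("universe must contain every gene used in the sets")
  structure(list(sets = sets, universe = universe), class = "GeneSetCollection")
}

#' Read a survival table
#'
#' A delimited table with columns `sample`, `time` (non-negative durations)
#' and `event` (1/TRUE = death observed, 0/FALSE = censored).
#'
#' @param path path to the TSV file.
#' @return an object of class `SurvivalTable`: data.frame with columns
#'   `sample`, `time`, `event`.
#' @export
read_survival <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample", "time", "event") %in% names(tab)))
    stop("survival table must have 'sample', 'time' and 'event' columns")
  survival_table(tab$sample, tab$time, tab$event)
}

#' Construct a survival table
#'
#' @param sample sample identifiers.
#' @param time non-negative survival/censoring durations.
#' @param event logical or 0/1: was death observed.
#' @return a `SurvivalTable` data.frame.
#' @export
survival_table <- function(sample, time, event) {
  if (length(sample) != length(time) || length(time) != length(event))
    stop("sample, time and event must have equal lengths")
  time <- as.numeric(time)
  if (any(is.na(time)) || any(time < 0)) stop("time must be non-negative")
  event <- as.logical(event)
  if (any(is.na(event))) stop("event must be logical or 0/1")
  structure(data.frame(sample = as.character(sample), time = time,
                       event = event, stringsAsFactors = FALSE),
            class = c("SurvivalTable", "data.frame"))
}
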