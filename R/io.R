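#' Read / write FACS-style time courses as CSV
#'
#' Column layout: `time_days`, `count_hi`, `count_lo`, `fraction_lo`.
#'
#' @param tc A `timecourse` data frame.
#' @param path File path.
#' @return `read_timecourse` returns a `timecourse` data frame;
#'   `write_timecourse` returns `path` invisibly.
#' @export
write_timecourse <- function(tc, path) {
  utils::write.csv(as.data.frame(tc)[, c("time_days", "count_hi", "count_lo", "fraction_lo")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_days", "count_hi", "count_lo", "fraction_lo")
  if (!all(need %in% names(d))) {
    stop("time-course CSV needs columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!is.na(d$fraction_lo) & (d$fraction_lo < 0 | d$fraction_lo > 1))
  if (length(bad)) stop("fraction_lo outside [0, 1] at rows: ", paste(bad, collapse = ", "))
  structure(d[need], class = c("timecourse", "data.frame"))
}

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line, tab-separated `name`, `description`, members.
#'
#' @param path GMT file path.
#' @param sets Named list of gene-identifier vectors.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  if (any(lengths(sets) == 0L)) stop("GMT contains an empty gene set")
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) stop("gene sets must be named")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-gene-per-line gene list
#' @param path Text file, one identifier per line; blanks ignored.
#' @return Character vector of unique identifiers.
#' @export
read_gene_list <- function(path) {
  g <- trimws(readLines(path, warn = FALSE))
  unique(g[nzchar(g)])
}

#' Read / write an expression matrix as TSV
#'
#' Genes as rows (first column `gene`), cells/samples as remaining columns.
#'
#' @param X Numeric matrix with dimnames.
#' @param path TSV path.
#' @return `read_matrix_tsv` returns a numeric matrix.
#' @export
write_matrix_tsv <- function(X, path) {
  d <- data.frame(gene = rownames(X), X, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "gene") stop("matrix TSV must have a leading 'gene' column")
  if (anyDuplicated(d$gene)) stop("duplicate gene identifiers in matrix")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene
  m
}

#' Read / write a count matrix as an MTX triplet
#'
#' Writes `<prefix>.mtx` (MatrixMarket sparse), `<prefix>.genes.txt`, and
#' `<prefix>.cells.txt`.
#'
#' @param X Matrix with dimnames (genes x cells).
#' @param prefix Path prefix for the three files.
#' @return `read_matrix_mtx` returns a dense base matrix with dimnames.
#' @export
write_matrix_mtx <- function(X, prefix) {
  Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE), paste0(prefix, ".mtx"))
  writeLines(rownames(X), paste0(prefix, ".genes.txt"))
  writeLines(colnames(X), paste0(prefix, ".cells.txt"))
  invisible(prefix)
}

#' @rdname write_matrix_mtx
#' @export
read_matrix_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, ".genes.txt"))
  colnames(m) <- readLines(paste0(prefix, ".cells.txt"))
  m
}

#' Write per-cell EMT scores as CSV
#'
#' Columns: `cell_id`, `E`, `M`, `EMT`, `pEMT`, `rank`, `hybrid_flag`.
#'
#' @param scores An [emt_pemt()] result.
#' @param path CSV path.
#' @param hybrid Optional logical vector from [hybrid_cells()].
#' @export
write_cell_scores <- function(scores, path, hybrid = NULL) {
  d <- as.data.frame(scores)
  d$hybrid_flag <- if (is.null(hybrid)) NA else as.integer(hybrid)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a survival table as CSV
#'
#' Columns `sample_id`, `time`, `event` (0/1), optional `group`.
#'
#' @param surv Data frame.
#' @param path CSV path.
#' @return `read_survival` returns a validated data frame.
#' @export
write_survival <- function(surv, path) {
  utils::write.csv(surv, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival
#' @export
read_survival <- function(path) {
  d <- utils::read.csv(path)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(d))) stop("survival CSV needs columns: ", paste(need, collapse = ", "))
  if (any(d$time < 0)) stop("survival times must be non-negative")
  if (!all(d$event %in% c(0, 1))) stop("event must be 0 or 1")
  d
}
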