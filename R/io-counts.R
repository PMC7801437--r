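#' Construct a gene-by-cell count matrix with per-cell annotations
#'
#' The central expression container: an integer matrix of raw counts
#' (genes as rows, cells as columns) plus one annotation record per cell
#' giving the donor (`individual`), the `cell_type` (`"alpha"`, `"beta"`
#' or `"other"`) and the sequencing `platform` (`"inDrops"`,
#' `"FluidigmC1"` or `"CelSeq2"`).
#'
#' @param counts integer matrix, genes x cells, with unique dimnames.
#' @param cell_meta data.frame with columns `cell`, `individual`,
#'   `cell_type`, `platform`; one row per column of `counts`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, cell_meta) {
  if (!is.matrix(counts)) stop_ctx("'counts' must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_ctx("'counts' needs gene rownames and cell colnames")
  if (anyDuplicated(rownames(counts))) stop_ctx("gene ids must be unique")
  if (anyDuplicated(colnames(counts))) stop_ctx("cell ids must be unique")
  if (any(is.na(counts)) || any(counts < 0))
    stop_ctx("counts must be non-negative and non-missing")
  if (any(counts != round(counts)))
    stop_ctx("validation error: counts must be integers")
  storage.mode(counts) <- "integer"
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  need <- c("cell", "individual", "cell_type", "platform")
  if (!all(need %in% names(cell_meta)))
    stop_ctx("cell_meta must have columns ", paste(need, collapse = ", "))
  if (!setequal(cell_meta$cell, colnames(counts)) ||
      nrow(cell_meta) != ncol(counts))
    stop_ctx("every cell must have exactly one meta record")
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$cell), , drop = FALSE]
  rownames(cell_meta) <- NULL
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  individuals: %s\n",
              paste(unique(x$cell_meta$individual), collapse = ", ")))
  cat(sprintf("  cell types:  %s\n",
              paste(names(table(x$cell_meta$cell_type)), collapse = ", ")))
  invisible(x)
}

#' Subset a count matrix to a set of cells (order preserved)
#' @param m a [count_matrix()].
#' @param cells character vector of cell ids to keep.
#' @return A `count_matrix` restricted to `cells`.
#' @export
subset_cells <- function(m, cells) {
  stopifnot(inherits(m, "count_matrix"))
  keep <- colnames(m$counts) %in% cells
  if (!any(keep)) stop_ctx("no cells left after subsetting")
  count_matrix(m$counts[, keep, drop = FALSE],
               m$cell_meta[m$cell_meta$cell %in% cells, , drop = FALSE])
}

check_int_counts <- function(v, path) {
  bad <- which(is.na(v) | v != round(v))
  if (length(bad))
    stop_ctx("validation error: non-integer count in ", path,
             " (entry ", bad[1], ")")
}

#' Read a count matrix from TSV or MatrixMarket triplet files
#'
#' TSV layout: genes as rows, first column gene id, header row of cell
#' ids. MatrixMarket layout: `<path>` is the `.mtx` file with co-located
#' `genes.tsv` (gene ids) and `barcodes.tsv` (cell ids), one id per line.
#' Cell annotations are supplied either in a `cells.tsv` next to the
#' matrix (TSV with header `cell individual cell_type platform`) or via
#' `cell_meta`.
#'
#' @param path file path (TSV matrix or `.mtx`).
#' @param format `"tsv"` or `"mtx-triplet"`.
#' @param cell_meta optional data.frame of per-cell annotations,
#'   overriding any `cells.tsv`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx-triplet"),
                              cell_meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_ctx("file not found: ", path)
  if (format == "tsv") {
    tab <- tryCatch(
      read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                 row.names = 1, colClasses = "character"),
      error = function(e) stop_ctx("parse error in ", path, ": ",
                                   conditionMessage(e)))
    counts <- suppressWarnings(
      matrix(as.numeric(as.matrix(tab)), nrow = nrow(tab),
             dimnames = list(rownames(tab), colnames(tab))))
    if (any(is.na(counts))) {
      bad <- which(is.na(counts), arr.ind = TRUE)[1, ]
      stop_ctx("parse error in ", path, " at data line ", bad[1],
               ": not a number")
    }
    check_int_counts(counts, path)
    dir <- dirname(path)
  } else {
    dir <- dirname(path)
    gfile <- file.path(dir, "genes.tsv")
    bfile <- file.path(dir, "barcodes.tsv")
    if (!file.exists(gfile) || !file.exists(bfile))
      stop_ctx("mtx-triplet needs co-located genes.tsv and barcodes.tsv")
    mm <- tryCatch(Matrix::readMM(path),
                   error = function(e) stop_ctx("parse error in ", path,
                                                ": ", conditionMessage(e)))
    counts <- as.matrix(mm)
    check_int_counts(counts, path)
    rownames(counts) <- readLines(gfile)
    colnames(counts) <- readLines(bfile)
  }
  if (is.null(cell_meta)) {
    mfile <- file.path(dir, "cells.tsv")
    if (file.exists(mfile)) {
      cell_meta <- read.table(mfile, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    } else {
      cell_meta <- data.frame(cell = colnames(counts), individual = "NA",
                              cell_type = "other", platform = "FluidigmC1",
                              stringsAsFactors = FALSE)
    }
  }
  missing <- setdiff(colnames(counts), cell_meta$cell)
  if (length(missing))
    stop_ctx("cells with missing meta record: ",
             paste(head(missing, 5), collapse = ", "))
  cell_meta <- cell_meta[cell_meta$cell %in% colnames(counts), , drop = FALSE]
  count_matrix(counts, cell_meta)
}

#' Write a count matrix to TSV or MatrixMarket triplet files
#'
#' @param m a [count_matrix()].
#' @param path output path; for `"mtx-triplet"` the `.mtx` file
#'   (`genes.tsv`, `barcodes.tsv`, `cells.tsv` are written next to it).
#' @param format `"tsv"` or `"mtx-triplet"`. TSV also writes a
#'   `cells.tsv` side file with the annotations.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, format = c("tsv", "mtx-triplet")) {
  stopifnot(inherits(m, "count_matrix"))
  format <- match.arg(format)
  dir <- dirname(path)
  if (format == "tsv") {
    tab <- data.frame(gene = rownames(m$counts), m$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(m$counts, sparse = TRUE), path)
    writeLines(rownames(m$counts), file.path(dir, "genes.tsv"))
    writeLines(colnames(m$counts), file.path(dir, "barcodes.tsv"))
  }
  write.table(m$cell_meta, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
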