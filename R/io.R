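#' Write a count matrix as a CellRanger-style Matrix Market directory
#'
#' Emits `matrix.mtx` (1-based triplet per the MatrixMarket standard),
#' `features.tsv` (gene ids, no header), `barcodes.tsv` (cell ids, no
#' header) and, when cell annotations are supplied, `cells.tsv`
#' (cell, condition, cluster). A simulation's truth manifest is written as
#' `truth.json` so inference stages can be scored without ever reading it
#' as an input.
#'
#' @param x A `pmn_sim` from [simulate_counts()], or a genes x cells matrix.
#' @param dir Output directory (created if missing).
#' @param cells Optional tibble with at least a `cell` column matching the
#'   matrix's colnames; ignored when `x` is a `pmn_sim`.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(x, dir, cells = NULL) {
  if (inherits(x, "pmn_sim")) {
    cells <- x$cells
    truth <- x$truth
    x <- x$counts
  } else {
    truth <- NULL
  }
  assert_counts(x)
  if (nrow(x) == 0L || ncol(x) == 0L) abort("refusing to write an empty matrix")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- as_dgc(x)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  if (!is.null(cells)) {
    stopifnot(identical(cells$cell, colnames(m)))
    keep <- intersect(c("cell", "condition", "cluster"), names(cells))
    utils::write.table(cells[, keep], file.path(dir, "cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(truth)) {
    tj <- truth[setdiff(names(truth), "config")]
    tj$base_mean <- NULL
    tj$module_factors <- NULL
    tj$seed <- truth$config$seed
    jsonlite::write_json(tj, file.path(dir, "truth.json"),
                         dataframe = "columns", na = "null", auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read a Matrix Market count directory
#'
#' Inverse of [write_counts()]: reads `matrix.mtx` + `features.tsv` +
#' `barcodes.tsv` (and `cells.tsv` if present).
#'
#' @param dir Directory written by [write_counts()] or CellRanger.
#' @return List with `counts` (dgCMatrix, genes x cells) and `cells`
#'   (tibble or `NULL`).
#' @export
read_counts <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) abort(sprintf("no matrix.mtx under '%s'", dir))
  m <- as_dgc(Matrix::readMM(mtx))
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  cells_path <- file.path(dir, "cells.tsv")
  cells <- if (file.exists(cells_path)) {
    readr::read_tsv(cells_path, show_col_types = FALSE, progress = FALSE)
  }
  list(counts = m, cells = cells)
}
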