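#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows bind_cols n desc distinct rename
#'   row_number across pull relocate
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_chr map_lgl map2 pmap imap walk
#' @importFrom stats rnbinom runif rnorm rmultinom cor pt p.adjust prcomp
#'   hclust cutree as.dist var sd quantile setNames lm coef
#' @importFrom utils head
NULL

# genes x cells sparse matrix expected throughout
assert_counts <- function(x, arg = "counts") {
  if (!methods::is(x, "sparseMatrix") && !is.matrix(x)) {
    abort(sprintf("`%s` must be a (sparse) matrix of genes x cells", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must carry gene rownames and cell colnames", arg))
  }
  invisible(x)
}

as_dgc <- function(x) {
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# column index (cell) of every stored nonzero in a dgCMatrix
col_of_x <- function(m) rep.int(seq_len(ncol(m)), diff(m@p))

# per-cell detection (count > 0) indicator sums for a gene subset
detect_frac <- function(counts, cells) {
  m <- counts[, cells, drop = FALSE]
  Matrix::rowSums(m > 0) / length(cells)
}

# exact-rational threshold test: frac(k/n) >= f without float drift at 0.5 etc.
frac_at_least <- function(k, n, f) {
  k * 1e6 >= round(f * 1e6) * n
}

# tiny polynomial hash of a parameter list, for stage provenance headers
param_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# stage-stamped TSV writer: first line is a provenance comment
write_stage_tsv <- function(df, path, stage, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage=%s params=%s", stage, param_hash(params)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_stage_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
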