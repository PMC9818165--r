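#' Quality-control thresholds and normalization scale
#'
#' Cells are removed when the number of detected genes (nFeature, genes
#' with count > 0) is below `min_features` or above `max_features`, or when
#' the mitochondrial fraction of counts exceeds `max_mito_pct` percent.
#' All three removal inequalities are strict, so boundary cells (exactly
#' 200 or 3000 features, exactly 20 percent mitochondrial) are retained.
#' Mitochondrial genes are identified by a case-insensitive symbol prefix.
#'
#' @param min_features,max_features Detected-gene bounds (defaults 200, 3000).
#' @param max_mito_pct Mitochondrial percentage cap (default 20).
#' @param mito_prefix Gene-symbol prefix, matched case-insensitively
#'   (default `"mt-"`, covering mouse `mt-` and human `MT-`).
#' @param scale_factor Library-size scale for [log_normalize()] (default 10000).
#' @return A `qc_params` list.
#' @export
qc_params <- function(min_features = 200, max_features = 3000,
                      max_mito_pct = 20, mito_prefix = "mt-",
                      scale_factor = 1e4) {
  if (min_features >= max_features) abort("min_features must be < max_features")
  if (max_mito_pct < 0 || max_mito_pct > 100) abort("max_mito_pct must be in [0, 100]")
  if (scale_factor <= 0) abort("scale_factor must be positive")
  structure(list(min_features = min_features, max_features = max_features,
                 max_mito_pct = max_mito_pct, mito_prefix = mito_prefix,
                 scale_factor = scale_factor), class = "qc_params")
}

#' Per-cell quality-control report
#'
#' Computes nFeature (genes with count > 0) and the mitochondrial
#' percentage for every cell and applies the removal thresholds of
#' [qc_params()]. A cell with zero total counts fails with reason
#' `"empty"` rather than producing a division by zero.
#'
#' @param counts Raw integer counts, genes x cells.
#' @param params A [qc_params()].
#' @return A tibble (class `qc_report`) with columns cell, n_features,
#'   mito_pct, pass, reason (comma-separated failure reasons, `NA` when
#'   passing).
#' @export
#' @examples
#' m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(5, 3), dims = c(3, 2),
#'                           dimnames = list(c("a", "b", "mt-1"), c("c1", "c2")))
#' compute_qc(m, qc_params(min_features = 1))
compute_qc <- function(counts, params = qc_params()) {
  assert_counts(counts)
  m <- as_dgc(counts)
  total <- Matrix::colSums(m)
  n_feat <- Matrix::colSums(m > 0)
  is_mito <- startsWith(tolower(rownames(m)), tolower(params$mito_prefix))
  mito_counts <- if (any(is_mito)) Matrix::colSums(m[is_mito, , drop = FALSE]) else rep(0, ncol(m))
  mito_pct <- ifelse(total > 0, 100 * mito_counts / total, NA_real_)

  reasons <- pmap(list(total, n_feat, mito_pct), function(tot, nf, mp) {
    r <- character()
    if (tot == 0) r <- c(r, "empty")
    if (nf < params$min_features) r <- c(r, "min_features")
    if (nf > params$max_features) r <- c(r, "max_features")
    if (!is.na(mp) && mp > params$max_mito_pct) r <- c(r, "mito")
    r
  })
  out <- tibble(
    cell = colnames(m),
    n_features = unname(as.integer(n_feat)),
    total_counts = unname(as.numeric(total)),
    mito_pct = unname(as.numeric(mito_pct)),
    pass = unname(lengths(reasons) == 0L),
    reason = unname(map_chr(reasons, function(r) if (length(r)) paste(r, collapse = ",") else NA_character_))
  )
  class(out) <- c("qc_report", class(out))
  attr(out, "params") <- params
  out
}

#' Drop QC-failing cells from a count matrix
#'
#' @param counts Raw counts, genes x cells.
#' @param report A [compute_qc()] report for the same cells (computed with
#'   default parameters when omitted).
#' @return The matrix restricted to passing cells.
#' @export
filter_cells <- function(counts, report = compute_qc(counts)) {
  assert_counts(counts)
  keep <- report$cell[report$pass]
  counts[, colnames(counts) %in% keep, drop = FALSE]
}

#' Library-size log-normalization
#'
#' `value(g, c) = ln(1 + scale_factor * count(g, c) / total(c))`: counts are
#' scaled to a common library size and natural-log transformed with a
#' pseudocount of 1. Zeros map to zeros, so sparsity is preserved, and the
#' transform is invariant to multiplying a cell's counts by a constant.
#'
#' @param counts Raw counts of QC-passing cells (no zero-total cells).
#' @param params A [qc_params()] supplying `scale_factor`.
#' @return A `dgCMatrix` of normalized values, same dimnames.
#' @export
#' @examples
#' m <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(2, 1),
#'                           dimnames = list(c("a", "b"), "c1"))
#' log_normalize(m, qc_params())["a", "c1"]  # ln(1 + 10000/1)
log_normalize <- function(counts, params = qc_params()) {
  assert_counts(counts)
  m <- as_dgc(counts)
  total <- Matrix::colSums(m)
  if (any(total == 0)) {
    abort("zero-total cell in input; run compute_qc()/filter_cells() first")
  }
  m@x <- log1p(params$scale_factor * m@x / total[col_of_x(m)])
  m
}
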