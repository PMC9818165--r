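#' Read or build a marker panel
#'
#' A marker panel maps cell types to marker gene symbols, as printed in a
#' dot-plot of established markers. The default panel ships as an editable
#' TSV (`system.file("extdata", "markers.tsv", package = "pmniche")`).
#'
#' @param path TSV with columns `celltype` and `gene`; default the bundled
#'   mouse lung panel.
#' @return Tibble (celltype, gene); celltype order follows first appearance
#'   and is the tie-break order for annotation.
#' @export
marker_panel <- function(path = system.file("extdata", "markers.tsv", package = "pmniche")) {
  p <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("celltype", "gene") %in% names(p))) abort("panel needs columns celltype, gene")
  p
}

#' Annotate clusters by marker-panel z-scores
#'
#' For each cluster, the mean normalized expression of every panel gene is
#' computed, z-scored across clusters, and each cell type is scored as the
#' mean z of its markers; the cluster is assigned the argmax cell type.
#' Ties break by the panel's declaration order. Markers absent from the
#' matrix are dropped with a warning; a cell type whose markers are all
#' absent is skipped.
#'
#' @param norm Normalized matrix, genes x cells.
#' @param clusters Named character vector or tibble (cell, cluster) giving
#'   a cluster label for every cell of `norm`.
#' @param panel Marker panel tibble (celltype, gene), see [marker_panel()].
#' @return Tibble (class `cluster_annotation`): cluster, celltype, score,
#'   with the full cluster x celltype score matrix in `attr(, "scores")`.
#' @export
annotate_clusters <- function(norm, clusters, panel = marker_panel()) {
  assert_counts(norm, "norm")
  clusters <- as_cluster_vector(clusters, colnames(norm))
  panel <- filter(panel, !is.na(.data$gene))
  absent <- setdiff(unique(panel$gene), rownames(norm))
  if (length(absent)) {
    warn(sprintf("markers absent from matrix, dropped: %s", toString(absent)))
    panel <- filter(panel, !.data$gene %in% absent)
  }
  types <- unique(panel$celltype)
  if (length(types) == 0L) abort("no panel markers present in the matrix")

  cl_levels <- unique(clusters)
  genes <- unique(panel$gene)
  # cluster-mean profile of each panel gene
  prof <- vapply(cl_levels, function(cl) {
    Matrix::rowMeans(norm[genes, clusters == cl, drop = FALSE])
  }, numeric(length(genes)))
  prof <- matrix(prof, nrow = length(genes), dimnames = list(genes, cl_levels))
  # z-score each gene across clusters (constant rows -> 0)
  s <- apply(prof, 1, sd)
  z <- (prof - rowMeans(prof)) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0

  scores <- vapply(types, function(ty) {
    colMeans(z[panel$gene[panel$celltype == ty], , drop = FALSE])
  }, numeric(length(cl_levels)))
  scores <- matrix(scores, nrow = length(cl_levels), dimnames = list(cl_levels, types))

  best <- apply(scores, 1, function(row) types[which.max(row)])  # which.max: first max wins
  out <- tibble(cluster = cl_levels, celltype = unname(best),
                score = scores[cbind(cl_levels, unname(best))])
  attr(out, "scores") <- scores
  class(out) <- c("cluster_annotation", class(out))
  out
}

as_cluster_vector <- function(clusters, cells) {
  if (is.data.frame(clusters)) {
    clusters <- setNames(clusters$cluster, clusters$cell)
  }
  if (is.null(names(clusters))) {
    if (length(clusters) != length(cells)) abort("clusters must be named by cell or match ncol")
    names(clusters) <- cells
  }
  if (!all(cells %in% names(clusters))) abort("every cell needs a cluster label")
  unname_ok <- clusters[cells]
  if (anyNA(unname_ok)) abort("every cell needs a cluster label")
  as.character(unname_ok)
}

#' Two-condition cluster composition table
#'
#' Counts cells per (cluster, condition), computes within-condition
#' proportions and the log2 ratio of proportions (second condition over
#' first). A cluster empty in one condition gets a Haldane-style
#' pseudo-proportion `1 / (2 * n_condition)` so the ratio stays finite;
#' such rows are flagged.
#'
#' @param cells Tibble with columns cell, condition, cluster.
#' @param conditions Optional two condition labels fixing the ratio's
#'   orientation; default the order of first appearance.
#' @return Tibble (class `composition_table`): cluster, then per condition
#'   n_<cond> and prop_<cond>, log2_ratio, pseudo (flag).
#' @export
#' @examples
#' cells <- tibble::tibble(cell = as.character(1:6),
#'                         condition = rep(c("A", "B"), each = 3),
#'                         cluster = c("x", "x", "y", "x", "y", "y"))
#' composition_shift(cells)
composition_shift <- function(cells, conditions = NULL) {
  if (!all(c("cell", "condition", "cluster") %in% names(cells))) {
    abort("`cells` needs columns cell, condition, cluster")
  }
  conditions <- conditions %||% unique(cells$condition)
  if (length(conditions) != 2L) abort("exactly two conditions required")
  n_cond <- table(factor(cells$condition, levels = conditions))
  if (any(n_cond == 0)) abort("a condition has zero cells")

  tab <- cells |>
    count_(conditions) |>
    mutate(
      prop_1 = .data$n_1 / sum(.data$n_1),
      prop_2 = .data$n_2 / sum(.data$n_2),
      pseudo = .data$n_1 == 0 | .data$n_2 == 0,
      log2_ratio = log2(
        ifelse(.data$n_2 == 0, 1 / (2 * sum(.data$n_2)), .data$prop_2) /
          ifelse(.data$n_1 == 0, 1 / (2 * sum(.data$n_1)), .data$prop_1)
      )
    )
  names(tab) <- sub("_1$", paste0("_", conditions[1]), names(tab))
  names(tab) <- sub("_2$", paste0("_", conditions[2]), names(tab))
  attr(tab, "conditions") <- conditions
  class(tab) <- c("composition_table", class(tab))
  tab
}

count_ <- function(cells, conditions) {
  tab <- table(cluster = cells$cluster, condition = factor(cells$condition, levels = conditions))
  tibble(cluster = rownames(tab),
         n_1 = as.integer(tab[, 1]),
         n_2 = as.integer(tab[, 2]))
}
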