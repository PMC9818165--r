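#' Polarity marker sets
#'
#' Default N1 (anti-tumor) and N2 (pro-tumor) neutrophil markers: N1
#' Ccl3/Fas/Cxcl3/Tnf, N2 Mmp9/S100a8/S100a9/Arg1. Sets must be disjoint
#' and non-empty.
#'
#' @param n1,n2 Character vectors of gene symbols.
#' @return A `polarity_markers` list.
#' @export
polarity_markers <- function(n1 = c("Ccl3", "Fas", "Cxcl3", "Tnf"),
                             n2 = c("Mmp9", "S100a8", "S100a9", "Arg1")) {
  if (length(n1) == 0L || length(n2) == 0L) abort("marker sets must be non-empty")
  if (length(intersect(n1, n2))) abort("n1 and n2 marker sets must be disjoint")
  structure(list(n1 = n1, n2 = n2), class = "polarity_markers")
}

#' Per-cell N1/N2 polarization score
#'
#' Each marker gene's normalized expression is z-scored across the given
#' cells; the score is `mean(z of N2 markers) - mean(z of N1 markers)`, so
#' N2-skewed cells score positive, N1-skewed cells negative, and cells
#' expressing neither set sit near zero. Swapping the two sets negates
#' every score. Markers absent from the matrix are dropped with a warning;
#' an entirely absent set is an error.
#'
#' @param norm Normalized matrix, genes x cells.
#' @param cells Cell ids to score (default all columns).
#' @param markers A [polarity_markers()].
#' @return Tibble (cell, score).
#' @export
polarization_score <- function(norm, cells = colnames(norm), markers = polarity_markers()) {
  assert_counts(norm, "norm")
  use <- function(set, label) {
    present <- intersect(set, rownames(norm))
    if (length(present) == 0L) abort(sprintf("no %s markers present in the matrix", label))
    if (length(present) < length(set)) {
      warn(sprintf("%s markers absent, dropped: %s", label, toString(setdiff(set, present))))
    }
    present
  }
  n1 <- use(markers$n1, "n1")
  n2 <- use(markers$n2, "n2")
  m <- as.matrix(norm[c(n1, n2), cells, drop = FALSE])
  s <- apply(m, 1, sd)
  z <- (m - rowMeans(m)) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  score <- colMeans(z[n2, , drop = FALSE]) - colMeans(z[n1, , drop = FALSE])
  tibble(cell = cells, score = unname(score))
}

#' Rank-based marker-axis pseudotime
#'
#' Orders cells along the polarization axis: `t = (rank(score) - 1) /
#' (n - 1)`, ties sharing their average rank, so t lies in `[0, 1]` and is
#' invariant to any monotone transform of the scores. This is the package's
#' fully specified stand-in for a learned trajectory: downstream screening
#' only consumes gene-pseudotime associations, which a rank ordering
#' supports.
#'
#' @param scores Tibble (cell, score) from [polarization_score()], or a
#'   named numeric vector.
#' @return Tibble (cell, t). Constant scores give all `t = 0.5` with a
#'   warning.
#' @export
#' @examples
#' pseudotime_rank(tibble::tibble(cell = c("a", "b", "c"), score = c(-1, 0, 2)))
pseudotime_rank <- function(scores) {
  if (is.data.frame(scores)) scores <- setNames(scores$score, scores$cell)
  if (length(scores) < 3L) abort("need at least 3 cells to order")
  if (max(scores) == min(scores)) {
    warn("constant scores: pseudotime undefined, returning t = 0.5 for all cells")
    return(tibble(cell = names(scores), t = rep(0.5, length(scores))))
  }
  r <- rank(scores, ties.method = "average")
  tibble(cell = names(scores), t = unname((r - 1) / (length(scores) - 1)))
}

#' Screen genes for pseudotime association
#'
#' Spearman rank correlation of each gene's normalized expression with
#' pseudotime, over genes detected in at least `min_detect` of the cells
#' (the rest are skipped, which also keeps the Benjamini-Hochberg
#' correction from being diluted by never-detected genes). P-values use
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`. A gene is
#' called positively associated when `rho > min_abs_rho` and `q <= max_q`,
#' negatively when `rho < -min_abs_rho` and `q <= max_q`.
#'
#' @param norm Normalized matrix, genes x cells.
#' @param t Tibble (cell, t) from [pseudotime_rank()] or named vector.
#' @param min_abs_rho Association-strength threshold (default 0.3).
#' @param max_q BH false-discovery threshold (default 0.05).
#' @param min_detect Minimum detection fraction for a gene to be tested
#'   (default 0.05).
#' @return Tibble (class `pt_screen`): gene, rho, p_value, q_value,
#'   association (`pos` / `neg` / `none`), detect_frac.
#' @export
screen_pseudotime_genes <- function(norm, t, min_abs_rho = 0.3, max_q = 0.05,
                                    min_detect = 0.05) {
  assert_counts(norm, "norm")
  if (is.data.frame(t)) t <- setNames(t$t, t$cell)
  cells <- names(t)
  if (length(cells) < 10L) abort("fewer than 10 cells: correlation unstable")
  m <- norm[, cells, drop = FALSE]
  det <- Matrix::rowSums(m > 0) / length(cells)
  tested <- rownames(m)[det >= min_detect]
  if (length(tested) == 0L) abort("no gene passes the detection filter")

  mm <- as.matrix(m[tested, , drop = FALSE])
  rx <- t(apply(mm, 1, rank))              # Spearman = Pearson on ranks
  rho <- suppressWarnings(as.vector(cor(t(rx), rank(t))))
  rho[is.na(rho)] <- 0
  n <- length(cells)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")

  out <- tibble(
    gene = tested, rho = rho, p_value = p, q_value = q,
    detect_frac = unname(det[tested])
  ) |>
    mutate(association = dplyr::case_when(
      .data$rho > min_abs_rho & .data$q_value <= max_q ~ "pos",
      .data$rho < -min_abs_rho & .data$q_value <= max_q ~ "neg",
      .default = "none"
    )) |>
    arrange(desc(abs(.data$rho)), .data$gene)
  attr(out, "params") <- list(min_abs_rho = min_abs_rho, max_q = max_q,
                              min_detect = min_detect, n_cells = n)
  class(out) <- c("pt_screen", class(out))
  out
}

#' Hub genes: pseudotime-associated genes inside named modules
#'
#' Intersects the association-called genes of a pseudotime screen with the
#' union of the named co-expression modules' gene sets — the
#' trajectory x co-expression intersection used to nominate genes driving
#' a phenotypic transition. Order-independent and idempotent.
#'
#' @param screen A [screen_pseudotime_genes()] result.
#' @param modules A `module_set` from [detect_modules()].
#' @param module_ids Module labels to use (e.g. `c("M1", "M4")`).
#' @return Tibble: gene, module, association, rho, sorted by module then
#'   |rho| descending.
#' @export
hub_genes <- function(screen, modules, module_ids) {
  known <- setdiff(unique(modules$genes$module), "grey")
  bad <- setdiff(module_ids, known)
  if (length(bad)) abort(sprintf("unknown module id(s): %s", toString(bad)))
  called <- filter(screen, .data$association != "none")
  modules$genes |>
    filter(.data$module %in% module_ids) |>
    inner_join(select(called, "gene", "association", "rho"), by = "gene") |>
    arrange(.data$module, desc(abs(.data$rho)), .data$gene)
}
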