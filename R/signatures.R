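#' Call signature genes between two cell groups
#'
#' Implements the dual criterion used throughout the niche analysis: a gene
#' is a signature gene when it is detected (raw count > 0) in more than
#' `min_fraction` of the cells of at least one group, and its expression
#' differs by more than `min_log2fc` log2 units between the groups. Both
#' inequalities are strict (the printed thresholds are ">50%" and
#' "log2FC > 1", i.e. >2-fold). Fold change is computed on de-logged
#' normalized means: `mean_x = mean(exp(value) - 1)` over the group, and
#' `log2fc = log2((mean_a + pseudocount) / (mean_b + pseudocount))`.
#'
#' On log1p-normalized data a value is positive exactly when the raw count
#' was, so detection fractions are taken from the nonzeros of `norm`.
#'
#' @param norm Normalized matrix from [log_normalize()], genes x cells.
#' @param group_a,group_b Disjoint, non-empty character vectors of cell ids.
#' @param min_fraction Detection-fraction threshold (default 0.5, strict).
#' @param min_log2fc Fold-change threshold in log2 units (default 1, strict).
#' @param pseudocount Added to both means before the ratio (default 1).
#' @param rank_test Also annotate a two-sided Wilcoxon rank-sum p-value per
#'   gene (never used for calling; default `FALSE`).
#' @return Tibble (class `signature_result`) with per-gene fraction_a,
#'   fraction_b, mean_a, mean_b, log2fc, direction
#'   (`up_in_a` / `up_in_b` / `none`) and called, sorted by |log2fc|
#'   descending with ties broken by gene id.
#' @export
call_signatures <- function(norm, group_a, group_b,
                            min_fraction = 0.5, min_log2fc = 1,
                            pseudocount = 1, rank_test = FALSE) {
  assert_counts(norm, "norm")
  if (length(group_a) == 0L || length(group_b) == 0L) abort("both groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0L) abort("groups overlap")
  missing <- setdiff(c(group_a, group_b), colnames(norm))
  if (length(missing)) abort(sprintf("unknown cells: %s ...", head(missing, 3)))

  ma <- norm[, group_a, drop = FALSE]
  mb <- norm[, group_b, drop = FALSE]
  frac_a <- Matrix::rowSums(ma > 0) / length(group_a)
  frac_b <- Matrix::rowSums(mb > 0) / length(group_b)
  mean_a <- Matrix::rowSums(expm1_sparse(ma)) / length(group_a)
  mean_b <- Matrix::rowSums(expm1_sparse(mb)) / length(group_b)
  log2fc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))

  out <- tibble(
    gene = rownames(norm),
    fraction_a = unname(frac_a), fraction_b = unname(frac_b),
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    log2fc = unname(log2fc)
  ) |>
    mutate(
      called = (.data$fraction_a > min_fraction | .data$fraction_b > min_fraction) &
        abs(.data$log2fc) > min_log2fc,
      direction = dplyr::case_when(
        .data$called & .data$log2fc > 0 ~ "up_in_a",
        .data$called & .data$log2fc < 0 ~ "up_in_b",
        .default = "none"
      )
    ) |>
    arrange(desc(abs(.data$log2fc)), .data$gene)

  if (rank_test) {
    da <- as.matrix(ma)
    db <- as.matrix(mb)
    out$p_value <- map_dbl(out$gene, function(g) {
      stats::wilcox.test(da[g, ], db[g, ], exact = FALSE)$p.value
    })
  }
  attr(out, "params") <- list(min_fraction = min_fraction, min_log2fc = min_log2fc,
                              pseudocount = pseudocount)
  attr(out, "n_cells") <- c(a = length(group_a), b = length(group_b))
  class(out) <- c("signature_result", class(out))
  out
}

expm1_sparse <- function(m) {
  m@x <- expm1(m@x)
  m
}

#' Membership table and common intersection of named gene sets
#'
#' The Venn-diagram primitive used to intersect differential genes across
#' clusters: given two or more named sets, returns per-gene membership
#' flags and the genes common to every set. Order-independent.
#'
#' @param sets Named list of character vectors (at least two; empty sets
#'   allowed).
#' @return List with `membership` (tibble: gene, one logical column per
#'   set, n_sets) and `common` (character vector in all sets).
#' @export
#' @examples
#' venn_intersect(list(x = c("a", "b", "c"), y = c("b", "c", "d")))$common
venn_intersect <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) abort("`sets` must be named")
  if (length(sets) < 2L) abort("need at least two sets")
  genes <- sort(unique(unlist(sets)))
  membership <- tibble(gene = genes)
  for (nm in names(sets)) membership[[nm]] <- genes %in% sets[[nm]]
  membership$n_sets <- rowSums(as.matrix(membership[names(sets)]))
  common <- if (length(genes)) genes[membership$n_sets == length(sets)] else character()
  list(membership = membership, common = common)
}
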