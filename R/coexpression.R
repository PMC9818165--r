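#' Co-expression detection parameters
#'
#' @param soft_power Soft-threshold exponent beta for the adjacency
#'   `|cor|^beta`. `NULL` (default) picks the smallest beta in 1..12 whose
#'   adjacency gives a scale-free topology fit R^2 >= 0.8, falling back to
#'   6 (the WGCNA rule of thumb) when none qualifies.
#' @param min_module_size Smallest gene cluster kept as a module
#'   (default 30); smaller clusters go to the unassigned "grey" module.
#' @param n_top_genes Number of most-variable genes entered into the
#'   network (default 2000).
#' @param merge_corr Modules whose eigengenes correlate above this are
#'   merged (default 0.9).
#' @param cut_height_frac Static tree-cut height as a fraction of the
#'   dendrogram's maximum merge height (default 0.995).
#' @param pool Average each cell's normalized profile with its `pool_k`
#'   nearest cells (Euclidean distance in the selected gene space) before
#'   correlating — a lightweight smoothing for noisy inputs in the spirit
#'   of metacell aggregation (default `FALSE`).
#' @param pool_k Neighbourhood size for pooling (default 10).
#' @return A `coexpr_params` list.
#' @export
coexpr_params <- function(soft_power = NULL, min_module_size = 30,
                          n_top_genes = 2000, merge_corr = 0.9,
                          cut_height_frac = 0.995, pool = FALSE, pool_k = 10) {
  if (!is.null(soft_power) && soft_power < 1) abort("soft_power must be >= 1")
  if (merge_corr <= 0 || merge_corr >= 1) abort("merge_corr must be in (0, 1)")
  if (pool_k < 1) abort("pool_k must be >= 1")
  structure(list(soft_power = soft_power, min_module_size = min_module_size,
                 n_top_genes = n_top_genes, merge_corr = merge_corr,
                 cut_height_frac = cut_height_frac, pool = pool,
                 pool_k = pool_k), class = "coexpr_params")
}

# average each row (cell) with its k nearest rows, self included
pool_cells <- function(x, k) {
  d <- as.matrix(stats::dist(x))
  pooled <- x
  for (i in seq_len(nrow(x))) {
    nb <- order(d[i, ])[seq_len(min(k + 1, nrow(x)))]
    pooled[i, ] <- colMeans(x[nb, , drop = FALSE])
  }
  pooled
}

# soft-threshold adjacency of a cells x genes matrix: |Pearson cor|^beta.
# beta = 1 reduces to plain |correlation|; a_ii = 1 and the matrix is
# symmetric by construction.
soft_adjacency <- function(x, beta) {
  a <- abs(cor(x))^beta
  diag(a) <- 1
  a
}

# scale-free topology fit R^2 for an adjacency matrix (WGCNA-style binned fit)
scale_free_r2 <- function(adj, n_bins = 10) {
  k <- colSums(adj) - 1
  if (max(k) <= min(k)) return(0)
  bins <- cut(k, breaks = n_bins)
  df <- tibble(k = k, bin = bins) |>
    group_by(.data$bin) |>
    summarise(mk = mean(.data$k), p = n(), .groups = "drop") |>
    filter(.data$mk > 0, .data$p > 0)
  if (nrow(df) < 3) return(0)
  fit <- lm(log10(p) ~ log10(mk), data = df)
  summary(fit)$r.squared
}

#' Detect co-expression modules and their eigengenes
#'
#' A lightweight, fully specified take on weighted co-expression network
#' analysis: the `n_top_genes` most variable genes are correlated across
#' cells (Pearson on normalized expression), the adjacency is
#' `|cor|^beta` with a soft power chosen for approximate scale-free
#' topology, genes are clustered by average-linkage on `1 - adjacency`,
#' and the tree is cut statically at `cut_height_frac` of the maximum
#' merge height. Clusters below `min_module_size` are left unassigned
#' ("grey"). Each module's eigengene is the first principal component of
#' its gene-standardized submatrix, scaled to unit variance and
#' sign-oriented so the mean gene-eigengene correlation is positive;
#' modules with eigengene correlation above `merge_corr` are merged
#' iteratively. Surviving modules are labelled M1, M2, ... by decreasing
#' size. (Deliberate divergences from the reference tooling — no
#' topological-overlap transform, no dynamic tree cut, no metacell
#' pooling — are documented in the vignette.)
#'
#' @param norm Normalized matrix, genes x cells.
#' @param cells Cell ids to use (default all).
#' @param params A [coexpr_params()].
#' @return A `module_set` list: `genes` (tibble gene, module), `eigengenes`
#'   (tibble cell + one column per module), `sizes`, `soft_power`,
#'   `fit_r2`, `params`.
#' @export
detect_modules <- function(norm, cells = colnames(norm), params = coexpr_params()) {
  assert_counts(norm, "norm")
  if (length(cells) < max(50, params$min_module_size)) {
    abort("too few cells for module detection")
  }
  x <- as.matrix(Matrix::t(norm[, cells, drop = FALSE]))  # cells x genes
  v <- apply(x, 2, var)
  x <- x[, v > 0, drop = FALSE]
  v <- v[v > 0]
  keep <- names(sort(v, decreasing = TRUE))[seq_len(min(params$n_top_genes, length(v)))]
  if (length(keep) < 2 * params$min_module_size) {
    abort("too few variable genes for module detection")
  }
  x <- x[, keep, drop = FALSE]
  if (isTRUE(params$pool)) x <- pool_cells(x, params$pool_k)
  cmat <- soft_adjacency(x, 1)

  beta <- params$soft_power
  fit_r2 <- NA_real_
  if (is.null(beta)) {
    beta <- 6L
    for (b in 1:12) {
      r2 <- scale_free_r2(cmat^b)
      if (r2 >= 0.8) { beta <- b; fit_r2 <- r2; break }
    }
  }
  adj <- cmat^beta
  if (is.na(fit_r2)) fit_r2 <- scale_free_r2(adj)

  tree <- hclust(as.dist(1 - adj), method = "average")
  labels0 <- cutree(tree, h = params$cut_height_frac * max(tree$height))
  sizes0 <- table(labels0)
  assigned <- names(sizes0)[sizes0 >= params$min_module_size]
  module_of <- ifelse(labels0 %in% assigned, as.character(labels0), "grey")
  names(module_of) <- colnames(x)

  eg <- function(genes_in) {
    sub <- scale(x[, genes_in, drop = FALSE])
    sub[, apply(x[, genes_in, drop = FALSE], 2, var) == 0] <- 0
    e <- prcomp(sub, center = FALSE, scale. = FALSE)$x[, 1]
    if (sd(e) > 0) e <- e / sd(e)
    if (mean(cor(e, sub), na.rm = TRUE) < 0) e <- -e
    e
  }

  mods <- setdiff(unique(module_of), "grey")
  eigengenes <- lapply(mods, function(m) eg(names(module_of)[module_of == m]))
  names(eigengenes) <- mods

  # iterative merge of near-identical eigengenes
  repeat {
    if (length(mods) < 2) break
    em <- do.call(cbind, eigengenes[mods])
    cc <- cor(em)
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] <= params$merge_corr) break
    a <- mods[mx[1]]; b <- mods[mx[2]]
    module_of[module_of == b] <- a
    eigengenes[[a]] <- eg(names(module_of)[module_of == a])
    eigengenes[[b]] <- NULL
    mods <- setdiff(mods, b)
  }

  # relabel by decreasing size
  sz <- sort(table(module_of[module_of != "grey"]), decreasing = TRUE)
  relabel <- setNames(paste0("M", seq_along(sz)), names(sz))
  final <- ifelse(module_of == "grey", "grey", relabel[module_of])
  eigengenes <- setNames(eigengenes[names(sz)], relabel[names(sz)])

  genes_tbl <- tibble(gene = names(module_of), module = unname(final))
  eg_tbl <- tibble(cell = cells)
  for (m in names(eigengenes)) eg_tbl[[m]] <- unname(eigengenes[[m]])

  out <- list(
    genes = genes_tbl,
    eigengenes = eg_tbl,
    sizes = as.integer(table(factor(genes_tbl$module,
                                    levels = c(names(eigengenes), "grey")))),
    soft_power = beta,
    fit_r2 = fit_r2,
    params = params
  )
  names(out$sizes) <- c(names(eigengenes), "grey")
  class(out) <- "module_set"
  out
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> %d modules (beta = %d, scale-free R2 = %.2f)\n",
              sum(names(x$sizes) != "grey"), x$soft_power, x$fit_r2))
  print(x$sizes)
  invisible(x)
}

#' Correlate module eigengenes with cell-level traits
#'
#' Pearson correlation of each module eigengene with each trait — a
#' condition indicator, a cluster-membership indicator, or any numeric
#' per-cell covariate — with a two-sided p-value from the t
#' approximation. Signs are reported so "module positively correlated
#' with trait" claims are machine-checkable. A constant trait yields `NA`
#' with a warning.
#'
#' @param modules A `module_set` from [detect_modules()].
#' @param traits Tibble with a `cell` column plus one numeric/logical
#'   column per trait, covering the module set's cells.
#' @return Tibble: module, trait, correlation, p_value.
#' @export
module_trait_correlation <- function(modules, traits) {
  eg <- modules$eigengenes
  if (!all(eg$cell %in% traits$cell)) abort("traits must cover all module-set cells")
  traits <- traits[match(eg$cell, traits$cell), ]
  mods <- setdiff(names(eg), "cell")
  trs <- setdiff(names(traits), "cell")
  n <- nrow(eg)
  out <- tidyr::expand_grid(module = mods, trait = trs) |>
    mutate(correlation = purrr::map2_dbl(.data$module, .data$trait, function(m, tr) {
      y <- as.numeric(traits[[tr]])
      if (sd(y) == 0) {
        warn(sprintf("trait '%s' is constant; correlation undefined", tr))
        return(NA_real_)
      }
      cor(eg[[m]], y)
    })) |>
    mutate(
      p_value = {
        r <- .data$correlation
        tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
        2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
      }
    )
  out
}
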