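#' Simulate a two-condition single-cell count matrix with planted truth
#'
#' Samples the generative world described by a [sim_config()]: negative
#' binomial counts per gene and cell, with planted cluster markers,
#' condition contrasts, an N1/N2 polarization gradient, shared-factor
#' co-expression modules, condition-patterned ligand-receptor elevations,
#' and a constructed low-quality cell fraction. A single RNG stream is
#' seeded once from `config$seed`, so the output (including the written
#' `.mtx`) is byte-reproducible.
#'
#' @param config A [sim_config()].
#' @return A `pmn_sim` list with elements
#'   * `counts`: sparse `dgCMatrix`, genes x cells, raw integer counts;
#'   * `cells`: tibble of per-cell truth (cell, condition, cluster,
#'     pseudotime, is_lowq);
#'   * `truth`: manifest list with planted markers, condition contrasts,
#'     module memberships, ligand-receptor edges, per-gene baseline means
#'     and the full multiplicative effect table.
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 300, n_cells = c(WT = 50, TB = 50)))
#' dim(sim$counts)
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config()")
  cfg <- config
  set.seed(cfg$seed)

  ## ---- gene universe -------------------------------------------------
  named <- sim_named_genes(cfg)
  module_genes <- if (cfg$n_modules > 0) {
    map(seq_len(cfg$n_modules), function(m) {
      sprintf("mod%d.g%02d", m, seq_len(cfg$module_size))
    })
  } else list()
  mito <- mouse_mito_genes
  hk <- if (cfg$n_housekeeping > 0) sprintf("hk%03d", seq_len(cfg$n_housekeeping)) else character()
  n_bg <- cfg$n_genes - length(named) - length(unlist(module_genes)) -
    length(mito) - length(hk)
  bg <- sprintf("g%04d", seq_len(n_bg))
  genes <- c(named, unlist(module_genes), mito, hk, bg)
  stopifnot(!anyDuplicated(genes))

  ## ---- baseline means ------------------------------------------------
  base_mean <- cfg$baseline_mean * exp(rnorm(length(genes), 0, 0.5))
  names(base_mean) <- genes
  marker_like <- unique(c(unlist(map(cfg$clusters, "markers")),
                          if (!is.null(cfg$gradient_cluster)) c(cfg$n1_markers, cfg$n2_markers),
                          if (!is.null(cfg$condition_de)) cfg$condition_de$gene))
  base_mean[marker_like] <- cfg$baseline_mean * cfg$marker_base_factor
  if (!is.null(cfg$gradient_cluster)) {
    base_mean[c(cfg$n1_markers, cfg$n2_markers)] <-
      cfg$baseline_mean * cfg$polarity_base_factor
  }
  if (!is.null(cfg$lr_truth)) {
    lr_genes <- setdiff(unique(c(cfg$lr_truth$ligand, cfg$lr_truth$receptor)), marker_like)
    base_mean[lr_genes] <- cfg$baseline_mean
  }
  base_mean[unlist(module_genes)] <- cfg$module_base_mean
  base_mean[hk] <- cfg$baseline_mean * cfg$housekeeping_mean_factor
  base_mean[mito] <- cfg$baseline_mean * cfg$mito_mean_factor

  ## ---- cells ---------------------------------------------------------
  cl_names <- map_chr(cfg$clusters, "name")
  cells <- map(cfg$conditions, function(cond) {
    n <- cfg$n_cells[[cond]]
    n_lowq <- round(cfg$lowq_fraction * n)
    n_main <- n - n_lowq
    prop <- map_dbl(cfg$clusters, function(cl) cl$abundance[[cond]])
    prop <- prop / sum(prop)
    cnt <- floor(prop * n_main)
    rem <- n_main - sum(cnt)
    if (rem > 0) { # largest-remainder rounding, deterministic
      ord <- order(prop * n_main - cnt, decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1L
    }
    tibble(
      condition = cond,
      cluster = c(rep(cl_names, cnt), rep("lowq", n_lowq)),
      is_lowq = c(rep(FALSE, n_main), rep(TRUE, n_lowq))
    )
  })
  cells <- bind_rows(cells)
  cells$cell <- sprintf("%s_cell%05d", cells$condition,
                        stats::ave(seq_len(nrow(cells)), cells$condition, FUN = seq_along))
  cells <- cells[, c("cell", "condition", "cluster", "is_lowq")]
  n_cell <- nrow(cells)

  ## ---- effect table (gene, cluster, condition-or-NA, log2fc) ---------
  effects <- bind_rows(
    bind_rows(map(cfg$clusters, function(cl) {
      tibble(gene = cl$markers, cluster = cl$name, condition = NA_character_,
             log2fc = cfg$marker_log2fc, role = "marker")
    })),
    if (!is.null(cfg$condition_de)) {
      mutate(cfg$condition_de, role = "condition_de")
    },
    if (!is.null(cfg$lr_truth)) {
      lr <- cfg$lr_truth
      cond_of <- function(p) dplyr::case_match(p, "gained" ~ cfg$conditions[2],
                                               "lost" ~ cfg$conditions[1],
                                               "shared" ~ NA_character_)
      bind_rows(
        tibble(gene = lr$ligand, cluster = lr$sender, condition = cond_of(lr$pattern),
               log2fc = cfg$lr_log2fc, role = "lr_ligand"),
        tibble(gene = lr$receptor, cluster = lr$receiver, condition = cond_of(lr$pattern),
               log2fc = cfg$lr_log2fc, role = "lr_receptor")
      )
    }
  )

  ## ---- mean matrix ---------------------------------------------------
  mu <- matrix(base_mean, nrow = length(genes), ncol = n_cell,
               dimnames = list(genes, cells$cell))
  if (nrow(effects)) {
    for (i in seq_len(nrow(effects))) {
      e <- effects[i, ]
      cols <- cells$cluster == e$cluster &
        (is.na(e$condition) | cells$condition == e$condition)
      mu[e$gene, cols] <- mu[e$gene, cols] * 2^e$log2fc
    }
  }

  # polarization gradient
  cells$pseudotime <- NA_real_
  if (!is.null(cfg$gradient_cluster)) {
    idx <- which(cells$cluster == cfg$gradient_cluster)
    t_true <- runif(length(idx))
    cells$pseudotime[idx] <- t_true
    g <- cfg$gradient_log2fc
    mu[cfg$n2_markers, idx] <- mu[cfg$n2_markers, idx] *
      rep(2^(g * t_true), each = length(cfg$n2_markers))
    mu[cfg$n1_markers, idx] <- mu[cfg$n1_markers, idx] *
      rep(2^(-g * t_true), each = length(cfg$n1_markers))
  }

  # module factors: one shared log-normal multiplier per module and cell
  module_factors <- NULL
  if (cfg$n_modules > 0) {
    module_factors <- matrix(NA_real_, n_cell, cfg$n_modules,
                             dimnames = list(cells$cell, paste0("mod", seq_len(cfg$n_modules))))
    for (m in seq_len(cfg$n_modules)) {
      f <- rnorm(n_cell, 0, cfg$module_factor_sd)
      link <- if (!is.null(cfg$module_condition)) cfg$module_condition[m] else NA
      if (!is.na(link)) {
        f <- f + log(2) * cfg$module_condition_shift * (cells$condition == link)
      }
      if (!is.null(cfg$module_gradient) && isTRUE(cfg$module_gradient[m])) {
        on_grad <- !is.na(cells$pseudotime)
        f[on_grad] <- f[on_grad] +
          log(2) * cfg$gradient_log2fc * (cells$pseudotime[on_grad] - 0.5)
      }
      module_factors[, m] <- f
      mu[module_genes[[m]], ] <- mu[module_genes[[m]], ] *
        rep(exp(f), each = cfg$module_size)
    }
  }

  # low-quality cells: construction guarantees <200 detected genes and
  # >20% mitochondrial content (counts drawn only on a small gene subset,
  # mitochondrial counts topped up to ~1/3 of the cell total)
  lowq_idx <- which(cells$is_lowq)
  lowq_subset <- setdiff(genes, mito)[seq_len(min(137L, length(genes) - length(mito)))]
  mu[, lowq_idx] <- 0

  ## ---- draw counts (one vectorised NB draw, gene-major within cell) --
  counts <- matrix(
    rnbinom(length(mu), mu = as.vector(mu), size = cfg$dispersion),
    nrow = nrow(mu), dimnames = dimnames(mu)
  )
  for (j in lowq_idx) {
    k <- rnbinom(length(lowq_subset), mu = base_mean[lowq_subset] * 3, size = cfg$dispersion)
    counts[lowq_subset, j] <- k
    m_tot <- ceiling(0.5 * sum(k)) + 1L
    counts[mito, j] <- as.vector(rmultinom(1, m_tot, rep(1, length(mito))))
  }

  truth <- list(
    cells = cells,
    markers = bind_rows(map(cfg$clusters, function(cl) tibble(cluster = cl$name, gene = cl$markers))),
    condition_de = cfg$condition_de,
    modules = if (cfg$n_modules > 0) {
      bind_rows(imap(module_genes, function(g, m) tibble(module = paste0("mod", m), gene = g)))
    },
    module_condition = cfg$module_condition,
    module_gradient = cfg$module_gradient,
    module_factors = module_factors,
    lr_edges = cfg$lr_truth,
    n1_markers = if (!is.null(cfg$gradient_cluster)) cfg$n1_markers,
    n2_markers = if (!is.null(cfg$gradient_cluster)) cfg$n2_markers,
    base_mean = base_mean,
    effects = effects,
    lowq_gene_subset = lowq_subset,
    config = cfg
  )
  class(truth) <- "pmn_truth"

  out <- list(counts = as_dgc(counts), cells = cells, truth = truth)
  class(out) <- "pmn_sim"
  out
}

#' Expected NB mean for a gene in a cluster/condition
#'
#' Reconstructs the configured (pre-gradient, pre-module-factor) negative
#' binomial mean `baseline x 2^(sum of planted log2 effects)` from a truth
#' manifest, for checking mean recovery.
#'
#' @param truth `truth` element of a [simulate_counts()] result.
#' @param gene,cluster,condition Identify the stratum.
#' @return A single expected mean.
#' @export
expected_mean <- function(truth, gene, cluster, condition) {
  e <- truth$effects
  lfc <- 0
  if (!is.null(e) && nrow(e)) {
    hit <- e$gene == gene & e$cluster == cluster &
      (is.na(e$condition) | e$condition == condition)
    lfc <- sum(e$log2fc[hit])
  }
  unname(truth$base_mean[gene] * 2^lfc)
}

#' @export
print.pmn_sim <- function(x, ...) {
  cat(sprintf("<pmn_sim> %d genes x %d cells (%s), %d clusters, %d low-quality\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$cells$condition), collapse = "/"),
              length(setdiff(unique(x$cells$cluster), "lowq")),
              sum(x$cells$is_lowq)))
  invisible(x)
}
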