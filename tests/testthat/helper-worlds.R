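# Small simulation worlds shared across tests. All fixtures are generated
# in code; nothing is read from disk.

# one homogeneous population, optional planted condition contrast
world_two_groups <- function(n_genes = 600, n_per_group = 150,
                             de_genes = character(), de_log2fc = 2.5,
                             seed = 1) {
  cde <- if (length(de_genes)) {
    tibble::tibble(gene = de_genes, cluster = "X", condition = "B",
                   log2fc = de_log2fc)
  }
  sim_config(
    n_genes = n_genes, n_cells = c(A = n_per_group, B = n_per_group),
    conditions = c("A", "B"),
    clusters = list(cluster_spec("X", "Csf1r", c(A = 1, B = 1))),
    condition_de = cde, gradient_cluster = NULL,
    lowq_fraction = 0, seed = seed
  )
}

# one cluster carrying the N1/N2 gradient
world_gradient <- function(n_genes = 500, n_per_group = 250, seed = 1) {
  sim_config(
    n_genes = n_genes, n_cells = c(WT = n_per_group, TB = n_per_group),
    clusters = list(cluster_spec("neutrophil", c("Cxcr2", "Ly6g"),
                                 c(WT = 1, TB = 1))),
    gradient_cluster = "neutrophil", lowq_fraction = 0, seed = seed
  )
}

# homogeneous population with two planted modules, second condition-linked
world_modules <- function(n_per_group = 300, seed = 1) {
  sim_config(
    n_genes = 2000, n_cells = c(WT = n_per_group, TB = n_per_group),
    clusters = list(cluster_spec("X", "Csf1r", c(WT = 1, TB = 1))),
    n_modules = 2, module_condition = c(NA, "TB"),
    gradient_cluster = NULL, lowq_fraction = 0, seed = seed
  )
}

# random small count matrix with dimnames, for oracle tests
random_counts <- function(n_genes, n_cells, lambda = 2, mito_rows = 0, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n_genes * n_cells, lambda), nrow = n_genes)
    rn <- sprintf("g%03d", seq_len(n_genes))
    if (mito_rows > 0) rn[seq_len(mito_rows)] <- sprintf("mt-%d", seq_len(mito_rows))
    dimnames(m) <- list(rn, sprintf("c%03d", seq_len(n_cells)))
    Matrix::Matrix(m, sparse = TRUE)
  })
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

best_module_match <- function(module_set, truth_genes) {
  ids <- setdiff(unique(module_set$genes$module), "grey")
  if (length(ids) == 0) return(list(id = NA_character_, jaccard = 0))
  js <- vapply(ids, function(d) {
    jaccard(truth_genes, module_set$genes$gene[module_set$genes$module == d])
  }, numeric(1))
  list(id = ids[which.max(js)], jaccard = max(js))
}
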