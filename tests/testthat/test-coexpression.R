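test_that("soft adjacency is symmetric with unit diagonal; beta = 1 is |cor|", {
  x <- withr::with_seed(3, matrix(stats::rnorm(200), 20, 10))
  a1 <- pmniche:::soft_adjacency(x, 1)
  expect_equal(a1, t(a1))
  expect_equal(unname(diag(a1)), rep(1, 10))
  expect_equal(a1, abs(cor(x)), tolerance = 1e-12)
  a3 <- pmniche:::soft_adjacency(x, 3)
  expect_equal(a3[1, 2], abs(cor(x))[1, 2]^3, tolerance = 1e-12)
  expect_true(all(a3[lower.tri(a3)] <= a1[lower.tri(a1)] + 1e-12))
})

test_that("a perfectly correlated module's eigengene equals its standardized genes", {
  n <- 80
  base <- withr::with_seed(9, stats::rnorm(n))
  cells <- sprintf("c%03d", 1:n)
  # 60 perfectly co-varying genes + 80 independent noise genes
  m <- rbind(
    matrix(rep(2 * base + 5, 60), nrow = 60, byrow = TRUE,
           dimnames = list(sprintf("mod%02d", 1:60), cells)),
    matrix(withr::with_seed(10, stats::rnorm(80 * n)), nrow = 80,
           dimnames = list(sprintf("bg%02d", 1:80), cells))
  )
  ms <- detect_modules(Matrix::Matrix(m, sparse = TRUE), cells,
                       coexpr_params(soft_power = 3, min_module_size = 30,
                                     n_top_genes = 140))
  mod_of <- setNames(ms$genes$module, ms$genes$gene)
  mod_ids <- unique(mod_of[sprintf("mod%02d", 1:60)])
  expect_length(mod_ids, 1L)
  expect_false(mod_ids == "grey")
  eg <- ms$eigengenes[[mod_ids]]
  z <- (base - mean(base)) / stats::sd(base)
  # the detected module may absorb an occasional noise gene, so the
  # eigengene matches the shared profile up to that contamination
  expect_gt(abs(cor(eg, z)), 0.999)
  # on the pure module alone the identity is exact
  pure <- detect_modules(Matrix::Matrix(m[1:60, ], sparse = TRUE), cells,
                         coexpr_params(soft_power = 3, min_module_size = 30,
                                       n_top_genes = 60))
  expect_equal(abs(cor(pure$eigengenes[[2]], z)), 1, tolerance = 1e-9)
  # unit variance, positively oriented to its member genes
  expect_equal(stats::sd(eg), 1, tolerance = 1e-9)
  expect_gt(cor(eg, m["mod01", ]), 0)
})

test_that("eigengene is the first principal component (optimality check)", {
  sim <- simulate_counts(world_modules(n_per_group = 100, seed = 31))
  norm <- log_normalize(sim$counts)
  ms <- detect_modules(norm, params = coexpr_params(soft_power = 3))
  id <- best_module_match(ms, sim$truth$modules$gene[sim$truth$modules$module == "mod1"])$id
  genes_in <- ms$genes$gene[ms$genes$module == id]
  x <- scale(as.matrix(Matrix::t(norm[genes_in, ms$eigengenes$cell])))
  eg <- ms$eigengenes[[id]]
  # brute-force eigendecomposition of the gene-gene covariance
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  pc1 <- as.vector(x %*% ev$vectors[, 1])
  expect_equal(abs(cor(eg, pc1)), 1, tolerance = 1e-6)
  # the first PC explains at least as much variance as any single
  # standardized member gene's projection
  var_along <- function(v) stats::var(as.vector(x %*% v / sqrt(sum(v^2))))
  for (k in withr::with_seed(2, sample(length(genes_in), 5))) {
    e_k <- rep(0, length(genes_in)); e_k[k] <- 1
    expect_gte(ev$values[1] + 1e-9, var_along(e_k))
  }
})

test_that("planted modules are recovered and background stays grey", {
  sim <- simulate_counts(world_modules(seed = 23))
  norm <- log_normalize(sim$counts)
  ms <- detect_modules(norm, params = coexpr_params(soft_power = 3))
  truth <- sim$truth$modules
  for (k in c("mod1", "mod2")) {
    bm <- best_module_match(ms, truth$gene[truth$module == k])
    expect_gte(bm$jaccard, 0.8)
  }
  bg <- setdiff(ms$genes$gene, truth$gene)
  expect_gte(mean(ms$genes$module[ms$genes$gene %in% bg] == "grey"), 0.95)
})

test_that("module detection is invariant to cell order and deterministic", {
  sim <- simulate_counts(world_modules(n_per_group = 100, seed = 37))
  norm <- log_normalize(sim$counts)
  p <- coexpr_params(soft_power = 3)
  ms1 <- detect_modules(norm, params = p)
  perm <- withr::with_seed(1, sample(colnames(norm)))
  ms2 <- detect_modules(norm[, perm], perm, p)
  g2 <- setNames(ms2$genes$module, ms2$genes$gene)
  expect_identical(setNames(ms1$genes$module, ms1$genes$gene),
                   g2[ms1$genes$gene])
  ms3 <- detect_modules(norm, params = p)
  expect_identical(ms1$genes, ms3$genes)
})

test_that("precondition violations error cleanly", {
  m <- random_counts(30, 30, seed = 2)
  expect_error(detect_modules(log_normalize(m)), "few cells")
  m2 <- random_counts(30, 80, seed = 2)
  expect_error(detect_modules(log_normalize(m2),
                              params = coexpr_params(min_module_size = 30)),
               "few variable genes")
})

test_that("module-trait correlation is signed and guards constant traits", {
  sim <- simulate_counts(world_modules(seed = 29))
  norm <- log_normalize(sim$counts)
  ms <- detect_modules(norm, params = coexpr_params(soft_power = 3))
  id2 <- best_module_match(ms, sim$truth$modules$gene[sim$truth$modules$module == "mod2"])$id

  traits <- tibble::tibble(
    cell = ms$eigengenes$cell,
    TB = as.integer(sim$cells$condition[match(ms$eigengenes$cell, sim$cells$cell)] == "TB"),
    flat = 1L
  )
  # identity: a trait equal to the eigengene correlates exactly 1
  traits$self <- ms$eigengenes[[id2]]
  expect_warning(mt <- module_trait_correlation(ms, traits), "constant")
  expect_equal(mt$correlation[mt$module == id2 & mt$trait == "self"], 1,
               tolerance = 1e-9)
  expect_true(is.na(mt$correlation[mt$module == id2 & mt$trait == "flat"]))
  # the condition-linked module correlates positively with its condition
  expect_gt(mt$correlation[mt$module == id2 & mt$trait == "TB"], 0)
  expect_lt(mt$p_value[mt$module == id2 & mt$trait == "TB"], 0.05)
})

test_that("pooling smooths profiles without changing their dimensions", {
  x <- withr::with_seed(8, matrix(stats::rnorm(50 * 20), 50, 20))
  px <- pmniche:::pool_cells(x, 5)
  expect_identical(dim(px), dim(x))
  # pooled columns have reduced variance across cells
  expect_lt(mean(apply(px, 2, var)), mean(apply(x, 2, var)))
})
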