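test_that("simulation is reproducible: same config and seed give identical output", {
  cfg <- world_gradient(n_genes = 300, n_per_group = 60, seed = 7)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(as.matrix(s1$counts), as.matrix(s2$counts))
  expect_identical(s1$cells, s2$cells)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_counts(s1, d1)
  write_counts(s2, d2)
  expect_identical(readLines(file.path(d1, "matrix.mtx")),
                   readLines(file.path(d2, "matrix.mtx")))
})

test_that("invalid configurations are rejected", {
  # overlapping planted polarity sets
  expect_error(
    sim_config(n1_markers = c("Mmp9", "Ccl3"), n2_markers = c("Mmp9"),
               gradient_cluster = "neutrophil"),
    "disjoint"
  )
  # abundances not summing to 1 - lowq_fraction
  expect_error(
    sim_config(clusters = list(cluster_spec("X", "Csf1r", c(WT = 0.5, TB = 0.5))),
               lowq_fraction = 0.05),
    "sum"
  )
  expect_error(sim_config(lowq_fraction = 1), "lowq_fraction")
  expect_error(
    sim_config(n_modules = 2, module_condition = "TB"),
    "per module"
  )
})

test_that("per-gene sample means recover the configured NB means", {
  # one cluster, one condition large enough for tight standard errors
  cfg <- sim_config(
    n_genes = 300, n_cells = c(A = 2100, B = 60), conditions = c("A", "B"),
    clusters = list(cluster_spec("X", "Csf1r", c(A = 1, B = 1))),
    gradient_cluster = NULL, lowq_fraction = 0, seed = 5
  )
  sim <- simulate_counts(cfg)
  a_cells <- sim$cells$cell[sim$cells$condition == "A"]
  m <- sim$counts[, a_cells]
  n <- length(a_cells)
  check <- c("Csf1r", "hk001", "mt-Nd1", rownames(m)[grepl("^g0", rownames(m))][1:5])
  for (g in check) {
    mu <- expected_mean(sim$truth, g, "X", "A")
    se <- sqrt((mu + mu^2 / cfg$dispersion) / n)
    expect_lt(abs(mean(m[g, ]) - mu), 3 * se + 1e-9,
              label = sprintf("gene %s mean error", g))
  }
  # marker elevated in its cluster: expected mean carries the 2^2.5 factor
  expect_equal(expected_mean(sim$truth, "Csf1r", "X", "A"),
               cfg$baseline_mean * cfg$marker_base_factor * 2^cfg$marker_log2fc)
})

test_that("the planted gradient drives N2 markers up and N1 markers down in t", {
  for (s in 1:5) {
    sim <- simulate_counts(world_gradient(n_per_group = 150, seed = 30 + s))
    t_true <- sim$cells$pseudotime
    for (g in sim$truth$n2_markers) {
      expect_gt(cor(as.numeric(sim$counts[g, ]), t_true, method = "spearman"), 0)
    }
    for (g in sim$truth$n1_markers) {
      expect_lt(cor(as.numeric(sim$counts[g, ]), t_true, method = "spearman"), 0)
    }
  }
})

test_that("low-quality construction: flagged cells violate QC, clean cells never do", {
  sim <- simulate_counts(sim_config(n_genes = 2000, n_cells = c(WT = 200, TB = 200),
                                    clusters = default_clusters(total = 0.9),
                                    lowq_fraction = 0.1, seed = 9))
  qc <- compute_qc(sim$counts)
  flagged <- sim$cells$is_lowq[match(qc$cell, sim$cells$cell)]
  expect_true(all(!qc$pass[flagged]))
  expect_true(all(qc$pass[!flagged]))
  # flagged cells violate by construction: few genes AND high mito
  expect_true(all(qc$n_features[flagged] < 200))
  expect_true(all(qc$mito_pct[flagged] > 20))
})

test_that("a zero lowq_fraction world passes QC wholesale", {
  sim <- simulate_counts(sim_config(n_genes = 2000, n_cells = c(WT = 80, TB = 80),
                                    clusters = default_clusters(total = 1),
                                    lowq_fraction = 0, seed = 2))
  qc <- compute_qc(sim$counts)
  expect_true(all(qc$pass))
})

test_that("an effect-free world is exchangeable between conditions", {
  # no planted difference of any kind: signature calls behave as a null
  cfg <- sim_config(n_genes = 800, n_cells = c(A = 200, B = 200),
                    conditions = c("A", "B"),
                    clusters = list(cluster_spec("X", "Csf1r", c(A = 1, B = 1))),
                    marker_log2fc = 0, gradient_cluster = NULL,
                    lowq_fraction = 0, seed = 11)
  sim <- simulate_counts(cfg)
  norm <- log_normalize(sim$counts)
  sig <- call_signatures(norm, sim$cells$cell[sim$cells$condition == "A"],
                         sim$cells$cell[sim$cells$condition == "B"])
  expect_lte(sum(sig$called), ceiling(0.01 * nrow(sig)))
})

test_that("matrix market round trip preserves the matrix and metadata", {
  sim <- simulate_counts(world_two_groups(n_genes = 200, n_per_group = 30, seed = 3))
  d <- withr::local_tempdir()
  write_counts(sim, d)

  # header declares genes x cells x nonzeros per the MM triplet standard
  lines <- readLines(file.path(d, "matrix.mtx"), n = 10)
  size_line <- lines[!startsWith(lines, "%")][1]
  dims <- as.integer(strsplit(trimws(size_line), "\\s+")[[1]])
  expect_identical(dims, c(nrow(sim$counts), ncol(sim$counts),
                           as.integer(Matrix::nnzero(sim$counts))))

  back <- read_counts(d)
  expect_identical(as.matrix(back$counts), as.matrix(sim$counts))
  expect_identical(back$cells$cell, sim$cells$cell)
  expect_identical(back$cells$cluster, sim$cells$cluster)
  expect_true(file.exists(file.path(d, "truth.json")))
})

test_that("writing an empty matrix is refused", {
  empty <- Matrix::Matrix(0, 0, 0, sparse = TRUE)
  expect_error(write_counts(empty, withr::local_tempdir()))
})
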