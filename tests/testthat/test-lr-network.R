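test_that("database merging unions, deduplicates and normalizes symbols", {
  t1 <- tibble::tibble(ligand = c("S100a6", "s100a6"), receptor = c("Anxa2", "ANXA2"),
                       source = "db1")
  t2 <- tibble::tibble(ligand = c("Cfh", "S100a6"), receptor = c("Itgam", "Anxa2"),
                       source = "db2")
  db <- merge_lr_databases(t1, t2)
  expect_identical(nrow(db), 2L)
  s <- db$source[db$ligand == "S100a6"]
  expect_match(s, "db1")
  expect_match(s, "db2")
  # deterministic lexicographic order
  expect_identical(db$ligand, sort(db$ligand))

  expect_warning(db0 <- merge_lr_databases(tibble::tibble(ligand = character(),
                                                          receptor = character())),
                 "empty|no pairs")
  expect_identical(nrow(db0), 0L)

  bad <- tibble::tibble(ligand = c("A", NA), receptor = c("B", "C"))
  expect_warning(db1 <- merge_lr_databases(bad), "malformed")
  expect_identical(nrow(db1), 1L)
  expect_identical(nrow(attr(db1, "rejected")), 1L)
})

test_that("expression fractions are exact at the 50 percent boundary", {
  m <- matrix(0, 2, 110, dimnames = list(c("L", "R"), sprintf("c%03d", 1:110)))
  cl <- c(rep("s", 10), rep("r", 100))
  m["L", 1:5] <- 3            # 5 of 10 sender cells: exactly 0.5
  m["R", 1:5] <- 2            # 0.5 in the sender cluster too
  m["R", 11:59] <- 2          # 49 of 100 receiver cells: 0.49
  fr <- expression_fractions(Matrix::Matrix(m, sparse = TRUE),
                             setNames(cl, colnames(m)))
  expect_equal(fr$fraction[fr$cluster == "s" & fr$gene == "L"], 0.5)
  expect_equal(fr$fraction[fr$cluster == "r" & fr$gene == "R"], 0.49)

  db <- tibble::tibble(ligand = "L", receptor = "R")
  edges <- call_interactions(fr, db, "A")
  # exactly 50% passes "at least 50%" on both ends; 49% fails
  expect_identical(nrow(edges), 1L)
  expect_identical(edges$sender, "s")
  expect_identical(edges$receiver, "s")
})

test_that("interaction calling applies the dual fraction rule over all cluster pairs", {
  fr <- tidyr::expand_grid(cluster = c("s", "r"), gene = c("L1", "L2", "R1")) |>
    dplyr::mutate(n_cells = 10L,
                  n_detected = c(6L, 2L, 5L,   1L, 1L, 9L),
                  fraction = n_detected / n_cells)
  db <- tibble::tibble(ligand = c("L1", "L2"), receptor = c("R1", "R1"))
  edges <- call_interactions(fr, db, "A")
  # L1 passes in s (0.6), R1 passes in s (0.5) and r (0.9):
  # edges s->s and s->r for (L1, R1); L2 passes nowhere
  expect_identical(nrow(edges), 2L)
  expect_setequal(edges$receiver, c("s", "r"))
  expect_true(all(edges$ligand == "L1"))
  expect_true(all(edges$sender == "s"))
})

test_that("raising the threshold never adds edges (monotonicity)", {
  sim <- simulate_counts(sim_config(n_genes = 500, n_cells = c(WT = 300, TB = 300),
                                    lr_truth = default_lr_truth(), seed = 51))
  qp <- qc_params(min_features = 40)  # floor scaled to the 500-gene universe
  norm <- log_normalize(filter_cells(sim$counts, compute_qc(sim$counts, qp)), qp)
  cells <- dplyr::filter(sim$cells, cell %in% colnames(norm), condition == "TB")
  db <- merge_lr_databases(default_lr_truth()[, c("ligand", "receptor")])
  fr <- expression_fractions(norm[, cells$cell], setNames(cells$cluster, cells$cell))
  key <- function(e) paste(e$sender, e$receiver, e$ligand, e$receptor)
  prev <- NULL
  for (f in c(0.3, 0.5, 0.7)) {
    e <- call_interactions(fr, db, "TB", min_fraction = f)
    if (!is.null(prev)) expect_true(all(key(e) %in% prev))
    prev <- key(e)
  }
})

test_that("differential networks obey the conservation identity on random edge sets", {
  for (s in 1:5) {
    all_edges <- tidyr::expand_grid(sender = c("a", "b"), receiver = c("a", "b"),
                                    ligand = sprintf("L%d", 1:5), receptor = "R")
    withr::with_seed(60 + s, {
      ea <- all_edges[sample(nrow(all_edges), 8), ]
      eb <- all_edges[sample(nrow(all_edges), 12), ]
    })
    ea$condition <- "A"; eb$condition <- "B"
    d <- differential_network(ea, eb)
    n <- table(factor(d$edges$status, levels = c("gained", "lost", "shared")))
    expect_identical(unname(n[["gained"]] + n[["lost"]] + 2L * n[["shared"]]),
                     nrow(ea) + nrow(eb))
  }
})

test_that("differential status labels follow their definitions", {
  e1 <- tibble::tibble(sender = "a", receiver = "b", ligand = "L1", receptor = "R1",
                       condition = "A")
  e2 <- tibble::tibble(sender = "a", receiver = "b", ligand = "L2", receptor = "R2",
                       condition = "B")
  d <- differential_network(e1, e2)
  expect_identical(d$edges$status[d$edges$ligand == "L1"], "lost")
  expect_identical(d$edges$status[d$edges$ligand == "L2"], "gained")

  # identical edge sets: everything shared
  d2 <- differential_network(e1, dplyr::mutate(e1, condition = "B"))
  expect_identical(unique(d2$edges$status), "shared")
  expect_identical(glance(d2)$shared, 1L)
})

test_that("planted gained and lost interactions are recovered exactly", {
  truth <- default_lr_truth()
  cfg <- sim_config(n_genes = 600, n_cells = c(WT = 500, TB = 500),
                    lr_truth = truth, lowq_fraction = 0.05, seed = 71)
  sim <- simulate_counts(cfg)
  # feature floor scaled to the 600-gene universe
  qp <- qc_params(min_features = 50)
  norm <- log_normalize(filter_cells(sim$counts, compute_qc(sim$counts, qp)), qp)
  cells <- dplyr::filter(sim$cells, cell %in% colnames(norm))
  db <- merge_lr_databases(truth[, c("ligand", "receptor")])
  edges <- lapply(c("WT", "TB"), function(cd) {
    cc <- dplyr::filter(cells, condition == cd)
    fr <- expression_fractions(norm[, cc$cell], setNames(cc$cluster, cc$cell))
    call_interactions(fr, db, cd)
  })
  d <- differential_network(edges[[1]], edges[[2]])
  got_gain <- dplyr::filter(d$edges, status == "gained")
  got_lost <- dplyr::filter(d$edges, status == "lost")
  want_gain <- dplyr::filter(truth, pattern == "gained")
  want_lost <- dplyr::filter(truth, pattern == "lost")
  expect_setequal(paste(got_gain$sender, got_gain$ligand, got_gain$receptor),
                  paste(want_gain$sender, want_gain$ligand, want_gain$receptor))
  expect_setequal(paste(got_lost$sender, got_lost$ligand, got_lost$receptor),
                  paste(want_lost$sender, want_lost$ligand, want_lost$receptor))
})
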