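#' Configure an end-to-end pipeline run
#'
#' Bundles the per-stage parameter blocks and the stage list for
#' [run_pipeline()]. The default configuration is the package's demo
#' world: the ten-cluster lung simulation with a neutrophil N1/N2
#' gradient, two planted co-expression modules (the second linked to the
#' tumor-bearing condition), and the planted ligand-receptor truth of
#' [default_lr_truth()].
#'
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param qc A [qc_params()].
#' @param lr_db Ligand-receptor database tibble; default the bundled
#'   `lr_pairs.tsv`.
#' @param panel Marker panel tibble; default the bundled `markers.tsv`.
#' @param signature_cluster Cluster for the within-cluster condition
#'   contrast (default `"monocyte"`).
#' @param polar_cluster Cluster carrying the polarization analysis
#'   (default `"neutrophil"`).
#' @param module_cells Which passing cells enter module detection:
#'   `"all"` (default) or a cluster name.
#' @param coexpr A [coexpr_params()].
#' @param stages Character vector of stages to run, in dependency order.
#' @param seed Integer seed for the whole run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, qc = qc_params(),
                            lr_db = NULL, panel = NULL,
                            signature_cluster = "monocyte",
                            polar_cluster = "neutrophil",
                            module_cells = "neutrophil",
                            coexpr = coexpr_params(soft_power = 3, min_module_size = 20),
                            stages = c("simulate", "qc", "annotate", "composition",
                                       "signatures", "polarize", "modules", "lrnet"),
                            seed = 1L) {
  if (is.null(sim)) {
    sim <- sim_config(
      n_modules = 3, module_condition = c(NA, "TB", NA),
      module_gradient = c(FALSE, FALSE, TRUE),
      gradient_cluster = "neutrophil",
      condition_de = tibble(
        gene = c("Slpi", "Wfdc17", "Apoc2", "Hp", "Fn1", "Irf8", "Jun"),
        cluster = "monocyte",
        condition = c(rep("TB", 5), rep("WT", 2)),
        log2fc = 2.5
      ),
      lr_truth = default_lr_truth(),
      seed = seed
    )
  }
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, qc = qc, lr_db = lr_db, panel = panel,
                 signature_cluster = signature_cluster,
                 polar_cluster = polar_cluster, module_cells = module_cells,
                 coexpr = coexpr, stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline into a directory
#'
#' Executes the enabled stages in dependency order — simulate, qc,
#' annotate, composition, signatures, polarize, modules, lrnet — logging
#' each stage's dimensions, and writes every table as a TSV stamped with
#' the producing stage and a parameter hash. A resolved copy of the
#' configuration is always written alongside the outputs, and a rerun with
#' the same configuration and seed reproduces every file byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; reused if existing).
#' @param verbose Log stage progress to the console (a `run.log` file is
#'   always written).
#' @return Invisibly, a list of in-memory stage results plus `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, verbose = FALSE) {
  if (!inherits(config, "pipeline_config")) abort("`config` must come from pipeline_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  say <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (verbose) message(msg)
  }
  writeLines(deparse(config[setdiff(names(config), c("lr_db", "panel"))]),
             file.path(out_dir, "resolved_config.txt"))
  on <- function(stage) stage %in% config$stages
  need <- function(x, stage) {
    if (is.null(x)) abort(sprintf("stage '%s' needs an upstream output that was not produced", stage))
    x
  }
  res <- list(out_dir = out_dir)

  if (on("simulate")) {
    res$sim <- simulate_counts(config$sim)
    write_counts(res$sim, file.path(out_dir, "sim"))
    say("simulate: %d genes x %d cells", nrow(res$sim$counts), ncol(res$sim$counts))
  }

  if (on("qc")) {
    sim <- need(res$sim, "qc")
    res$qc <- compute_qc(sim$counts, config$qc)
    write_stage_tsv(res$qc, file.path(out_dir, "qc_report.tsv"), "qc", config$qc)
    res$filtered <- filter_cells(sim$counts, res$qc)
    res$norm <- log_normalize(res$filtered, config$qc)
    res$cells <- filter(sim$cells, .data$cell %in% colnames(res$filtered))
    say("qc: %d / %d cells pass", ncol(res$filtered), ncol(sim$counts))
  }

  if (on("annotate")) {
    norm <- need(res$norm, "annotate")
    panel <- config$panel %||% marker_panel()
    res$annotation <- annotate_clusters(norm, res$cells, panel)
    write_stage_tsv(res$annotation, file.path(out_dir, "annotation.tsv"), "annotate", list())
    say("annotate: %d clusters", nrow(res$annotation))
  }

  if (on("composition")) {
    cells <- need(res$cells, "composition")
    res$composition <- composition_shift(cells, config$sim$conditions)
    write_stage_tsv(res$composition, file.path(out_dir, "composition.tsv"),
                    "composition", list())
    say("composition: %d clusters x 2 conditions", nrow(res$composition))
  }

  if (on("signatures")) {
    norm <- need(res$norm, "signatures")
    cl <- config$signature_cluster
    conds <- config$sim$conditions
    in_cl <- filter(res$cells, .data$cluster == cl)
    res$signatures <- call_signatures(
      norm,
      group_a = in_cl$cell[in_cl$condition == conds[2]],
      group_b = in_cl$cell[in_cl$condition == conds[1]]
    )
    write_stage_tsv(res$signatures,
                    file.path(out_dir, sprintf("signatures_%s.tsv", cl)),
                    "signatures", attr(res$signatures, "params"))
    say("signatures (%s, %s vs %s): %d called", cl, conds[2], conds[1],
        sum(res$signatures$called))
  }

  if (on("polarize")) {
    norm <- need(res$norm, "polarize")
    pc <- filter(res$cells, .data$cluster == config$polar_cluster)
    sc <- polarization_score(norm, pc$cell,
                             polarity_markers(config$sim$n1_markers, config$sim$n2_markers))
    res$pseudotime <- pseudotime_rank(sc)
    res$screen <- screen_pseudotime_genes(norm[, pc$cell, drop = FALSE], res$pseudotime)
    write_stage_tsv(res$pseudotime, file.path(out_dir, "pseudotime.tsv"), "polarize", list())
    write_stage_tsv(res$screen, file.path(out_dir, "screen.tsv"), "polarize",
                    attr(res$screen, "params"))
    say("polarize (%s): %d cells, %d associated genes", config$polar_cluster,
        nrow(pc), sum(res$screen$association != "none"))
  }

  if (on("modules")) {
    norm <- need(res$norm, "modules")
    use_cells <- if (identical(config$module_cells, "all")) res$cells$cell else {
      filter(res$cells, .data$cluster == config$module_cells)$cell
    }
    res$modules <- detect_modules(norm, use_cells, config$coexpr)
    traits <- tibble(cell = use_cells)
    cond2 <- config$sim$conditions[2]
    traits[[cond2]] <- as.integer(
      res$cells$condition[match(use_cells, res$cells$cell)] == cond2)
    res$module_trait <- module_trait_correlation(res$modules, traits)
    write_stage_tsv(res$modules$genes, file.path(out_dir, "modules.tsv"),
                    "modules", config$coexpr)
    write_stage_tsv(res$modules$eigengenes, file.path(out_dir, "eigengenes.tsv"),
                    "modules", config$coexpr)
    write_stage_tsv(res$module_trait, file.path(out_dir, "module_trait.tsv"),
                    "modules", config$coexpr)
    say("modules: %s", paste(sprintf("%s=%d", names(res$modules$sizes),
                                     res$modules$sizes), collapse = " "))
    if (!is.null(res$screen)) {
      ids <- setdiff(unique(res$modules$genes$module), "grey")
      if (length(ids)) {
        res$hubs <- hub_genes(res$screen, res$modules, ids)
        write_stage_tsv(res$hubs, file.path(out_dir, "hubs.tsv"), "modules", list())
        say("hubs: %d genes", nrow(res$hubs))
      }
    }
  }

  if (on("lrnet")) {
    norm <- need(res$norm, "lrnet")
    db <- config$lr_db %||% merge_lr_databases(
      readr::read_tsv(system.file("extdata", "lr_pairs.tsv", package = "pmniche"),
                      show_col_types = FALSE, progress = FALSE))
    conds <- config$sim$conditions
    genes_db <- unique(c(db$ligand, db$receptor))
    edges <- map(conds, function(cd) {
      cc <- filter(res$cells, .data$condition == cd)
      fr <- expression_fractions(norm[, cc$cell, drop = FALSE],
                                 setNames(cc$cluster, cc$cell), genes_db)
      e <- call_interactions(fr, db, cd)
      write_stage_tsv(e, file.path(out_dir, sprintf("edges_%s.tsv", cd)), "lrnet", list())
      e
    })
    res$lr_diff <- differential_network(edges[[1]], edges[[2]])
    write_stage_tsv(res$lr_diff$edges, file.path(out_dir, "diff_edges.tsv"), "lrnet", list())
    write_stage_tsv(res$lr_diff$summary, file.path(out_dir, "network_summary.tsv"),
                    "lrnet", list())
    say("lrnet: %d gained, %d lost, %d shared",
        sum(res$lr_diff$edges$status == "gained"),
        sum(res$lr_diff$edges$status == "lost"),
        sum(res$lr_diff$edges$status == "shared"))
  }

  invisible(res)
}
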