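#' Describe one simulated cell cluster
#'
#' A cluster is a named cell population with at least one marker gene and a
#' relative abundance per condition. Abundances of all clusters in a
#' [sim_config()] must sum, per condition, to `1 - lowq_fraction`.
#'
#' @param name Cluster label.
#' @param markers Character vector of marker gene symbols (non-empty). Marker
#'   genes are elevated by `marker_log2fc` log2 units in this cluster.
#' @param abundance Named numeric vector of per-condition proportions, names
#'   matching the config's `conditions`.
#' @return A `cluster_spec` list.
#' @export
#' @examples
#' cluster_spec("B", "Cd79a", c(WT = 0.14, TB = 0.10))
cluster_spec <- function(name, markers, abundance) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a single non-empty string")
  }
  if (length(markers) == 0L) abort(sprintf("cluster '%s': marker list must be non-empty", name))
  if (is.null(names(abundance)) || any(!nzchar(names(abundance)))) {
    abort(sprintf("cluster '%s': `abundance` must be named by condition", name))
  }
  if (any(abundance < 0 | abundance > 1)) {
    abort(sprintf("cluster '%s': abundances must lie in [0, 1]", name))
  }
  structure(list(name = name, markers = as.character(markers), abundance = abundance),
            class = "cluster_spec")
}

#' Default cluster panel for the simulated lung niche
#'
#' Ten populations mirroring a mouse lung immune/stromal map, with the marker
#' symbols conventionally used for each (Cd79a for B cells, Cd3e for T cells,
#' Ncr1 for NK, Cd3e+Klrb1c for NKT, Csf1r monocytes, Mrc1 macrophages,
#' Cd209a DCs, Cxcr2+Ly6g neutrophils, Pecam1+Cdh5 endothelium, Prox1
#' lymphatic endothelium). The tumor-bearing condition carries the niche-like
#' abundance shifts: neutrophils expand 5% to 20% and classical monocytes
#' 10% to 15%, with lymphoid and endothelial fractions compensating down.
#' Abundances per condition sum to 0.95, leaving 5% for planted low-quality
#' cells.
#'
#' @param conditions Two condition labels, default `c("WT", "TB")`
#'   (wild-type vs tumor-bearing).
#' @param total Per-condition abundance total, default 0.95; set 1 for a
#'   world with `lowq_fraction = 0`.
#' @return List of [cluster_spec()] objects.
#' @export
default_clusters <- function(conditions = c("WT", "TB"), total = 0.95) {
  ab <- function(a, b) setNames(c(a, b) * total / 0.95, conditions)
  list(
    cluster_spec("B",            "Cd79a",                 ab(0.14, 0.10)),
    cluster_spec("T",            "Cd3e",                  ab(0.18, 0.14)),
    cluster_spec("NK",           "Ncr1",                  ab(0.06, 0.05)),
    cluster_spec("NKT",          c("Cd3e", "Klrb1c"),     ab(0.04, 0.03)),
    cluster_spec("monocyte",     "Csf1r",                 ab(0.10, 0.15)),
    cluster_spec("macrophage",   "Mrc1",                  ab(0.12, 0.10)),
    cluster_spec("DC",           "Cd209a",                ab(0.05, 0.04)),
    cluster_spec("neutrophil",   c("Cxcr2", "Ly6g"),      ab(0.05, 0.20)),
    cluster_spec("EC",           c("Pecam1", "Cdh5"),     ab(0.14, 0.09)),
    cluster_spec("lymphatic_EC", "Prox1",                 ab(0.07, 0.05))
  )
}

#' Default planted ligand-receptor truth
#'
#' Seven planted sender->receiver pairs built on axes reported for the lung
#' niche (S100a6-Anxa2, Cfh-Itgam, Serpine2-Plaur gained in the tumor-bearing
#' lung; Icam1-Itgav and Lrg1-Acvrl1 lost), plus two constitutive (shared)
#' pairs. `pattern` is one of `"shared"` (both conditions), `"gained"`
#' (second condition only) or `"lost"` (first condition only).
#'
#' @return Tibble with columns ligand, receptor, sender, receiver, pattern.
#' @export
default_lr_truth <- function() {
  tibble::tribble(
    ~ligand,    ~receptor, ~sender,        ~receiver,    ~pattern,
    "S100a6",   "Anxa2",   "lymphatic_EC", "neutrophil", "gained",
    "Cfh",      "Itgam",   "monocyte",     "neutrophil", "gained",
    "Serpine2", "Plaur",   "lymphatic_EC", "macrophage", "gained",
    "Icam1",    "Itgav",   "lymphatic_EC", "EC",         "lost",
    "Lrg1",     "Acvrl1",  "lymphatic_EC", "EC",         "lost",
    "Apoe",     "Lrp1",    "macrophage",   "monocyte",   "shared",
    "Cxcl12",   "Cxcr4",   "EC",           "T",          "shared"
  )
}

mouse_mito_genes <- c(
  "mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp8", "mt-Atp6", "mt-Co3",
  "mt-Nd3", "mt-Nd4l", "mt-Nd4", "mt-Nd5", "mt-Nd6", "mt-Cytb"
)

#' Configure the synthetic two-condition scRNA-seq world
#'
#' Defines the ground-truth generative model sampled by [simulate_counts()].
#' Counts are negative binomial (mean/inverse-dispersion parameterisation,
#' `variance = mu + mu^2/dispersion`) with per-gene baseline means and
#' multiplicative planted effects expressed in log2 units:
#'
#' * marker genes of each cluster are elevated by `marker_log2fc` in that
#'   cluster (both conditions);
#' * `condition_de` plants within-cluster condition contrasts;
#' * cells of `gradient_cluster` receive a latent polarization pseudotime
#'   `t ~ Uniform(0, 1)`; N2 markers scale as `2^(gradient_log2fc * t)` and
#'   N1 markers as `2^(-gradient_log2fc * t)`;
#' * each co-expression module multiplies its member genes' means by a
#'   shared per-cell log-normal factor `exp(N(0, module_factor_sd))`; a
#'   condition-linked module additionally shifts the factor by
#'   `module_condition_shift` log2 units in its condition;
#' * ligand/receptor genes of `lr_truth` are elevated by `lr_log2fc` in the
#'   sender/receiver cluster under the stated condition pattern;
#' * a `lowq_fraction` of cells is constructed to fail quality control:
#'   fewer than 200 detected genes and over 20 percent mitochondrial counts.
#'
#' Planted marker and polarization genes get a deterministic baseline of
#' `baseline_mean * marker_base_factor` so that, at the planted effect size,
#' they are detected in well over half of their cells (well-expressed
#' markers); module genes get `module_base_mean`; ligand/receptor genes stay
#' at `baseline_mean` so their off-cluster detection fraction is low; the 13
#' mitochondrial genes (mouse `mt-` symbols) get
#' `baseline_mean * mito_mean_factor`, putting a healthy cell near 3-4
#' percent mitochondrial content. All other baselines are log-normal around
#' `baseline_mean`.
#'
#' @param n_genes Total genes simulated (planted + mitochondrial + background).
#' @param n_cells Named per-condition cell counts (default `c(WT = 1200, TB = 1000)`,
#'   a desk-scale version of a two-sample lung dataset).
#' @param clusters List of [cluster_spec()]; per condition the abundances must
#'   sum to `1 - lowq_fraction`.
#' @param conditions Two condition labels.
#' @param baseline_mean Scale of background gene NB means.
#' @param dispersion NB inverse-dispersion theta (shared across genes).
#' @param marker_log2fc Marker elevation in log2 units.
#' @param marker_base_factor Baseline multiplier for planted marker and
#'   condition-contrast genes.
#' @param polarity_base_factor Baseline multiplier for the N1/N2 polarity
#'   markers (default 25): granule-protein transcripts of the S100a8/a9
#'   class are among the most abundant in neutrophils, and the
#'   polarization score averages only a handful of genes, so these are
#'   simulated as highly expressed.
#' @param condition_de Optional tibble (gene, cluster, condition, log2fc) of
#'   planted within-cluster condition effects; gene symbols not already in
#'   the universe are added to it.
#' @param n_modules,module_size,module_factor_sd Planted co-expression
#'   modules: how many, genes per module, sd of the shared log-normal factor.
#' @param module_base_mean Baseline NB mean of module genes.
#' @param module_condition Optional character vector (length `n_modules`,
#'   `NA` entries allowed) linking modules to a condition.
#' @param module_condition_shift Log2 shift of a linked module's factor in
#'   its condition (default 0.5, i.e. 1.4-fold higher module activity;
#'   much larger shifts inflate the linked condition's library sizes and
#'   couple the module to every other gene through normalization).
#' @param module_gradient Optional logical vector (length `n_modules`): a
#'   gradient-coupled module's factor additionally follows the polarization
#'   pseudotime, `+ gradient_log2fc * log(2) * (t - 1/2)` in the gradient
#'   cluster, emulating a transition-linked co-expression program.
#' @param gradient_cluster Cluster carrying the N1/N2 gradient (`NULL` for none).
#' @param n1_markers,n2_markers Polarization marker genes (defaults: N1
#'   Ccl3/Fas/Cxcl3/Tnf, N2 Mmp9/S100a8/S100a9/Arg1).
#' @param gradient_log2fc Gradient effect size g.
#' @param lr_truth Tibble (ligand, receptor, sender, receiver, pattern) of
#'   planted interactions; see [default_lr_truth()].
#' @param lr_log2fc Elevation of planted ligand/receptor genes in their
#'   cluster (log2 units); the default 4 drives on-cluster detection to
#'   about 0.9 while off-cluster detection stays near 0.2.
#' @param lowq_fraction Fraction of cells planted as low quality, in `[0, 1)`.
#' @param n_housekeeping Number of constitutive high-expression genes
#'   (`hk...`); they carry a realistic share of each library so that no
#'   planted block dominates the per-cell total.
#' @param housekeeping_mean_factor Baseline multiplier for housekeeping
#'   genes (default 100, i.e. NB mean 20 at the default baseline).
#' @param mito_prefix Prefix naming mitochondrial genes.
#' @param mito_mean_factor Baseline multiplier for mitochondrial genes.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A validated `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 300, n_cells = c(WT = 60, TB = 60),
#'                   clusters = default_clusters(), lowq_fraction = 0.05)
sim_config <- function(n_genes = 2000,
                       n_cells = c(WT = 1200, TB = 1000),
                       clusters = default_clusters(conditions),
                       conditions = c("WT", "TB"),
                       baseline_mean = 0.2,
                       dispersion = 10,
                       marker_log2fc = 2.5,
                       marker_base_factor = 3,
                       polarity_base_factor = 25,
                       condition_de = NULL,
                       n_modules = 0,
                       module_size = 50,
                       module_factor_sd = 0.5,
                       module_base_mean = 5,
                       module_condition = NULL,
                       module_condition_shift = 0.5,
                       module_gradient = NULL,
                       gradient_cluster = NULL,
                       n1_markers = c("Ccl3", "Fas", "Cxcl3", "Tnf"),
                       n2_markers = c("Mmp9", "S100a8", "S100a9", "Arg1"),
                       gradient_log2fc = 2,
                       lr_truth = NULL,
                       lr_log2fc = 4,
                       lowq_fraction = 0.05,
                       n_housekeeping = 50,
                       housekeeping_mean_factor = 100,
                       mito_prefix = "mt-",
                       mito_mean_factor = 40,
                       seed = 1L) {
  if (length(conditions) != 2L || anyDuplicated(conditions)) {
    abort("`conditions` must be two distinct labels")
  }
  if (is.null(names(n_cells))) names(n_cells) <- conditions
  if (!setequal(names(n_cells), conditions)) {
    abort("`n_cells` must be named by the two conditions")
  }
  if (lowq_fraction < 0 || lowq_fraction >= 1) abort("`lowq_fraction` must be in [0, 1)")
  if (baseline_mean <= 0 || dispersion <= 0) abort("`baseline_mean` and `dispersion` must be positive")
  if (marker_log2fc < 0) abort("`marker_log2fc` must be >= 0")

  cl_names <- map_chr(clusters, "name")
  if (anyDuplicated(cl_names)) abort("cluster names must be unique")
  for (cond in conditions) {
    s <- sum(map_dbl(clusters, function(cl) {
      if (!cond %in% names(cl$abundance)) {
        abort(sprintf("cluster '%s' lacks an abundance for condition '%s'", cl$name, cond))
      }
      cl$abundance[[cond]]
    }))
    if (abs(s + lowq_fraction - 1) > 1e-8) {
      abort(sprintf(
        "cluster abundances for condition '%s' sum to %.4f; with lowq_fraction = %.3f they must sum to %.4f",
        cond, s, lowq_fraction, 1 - lowq_fraction))
    }
  }

  if (!is.null(gradient_cluster)) {
    if (!gradient_cluster %in% cl_names) {
      abort(sprintf("gradient_cluster '%s' is not a declared cluster", gradient_cluster))
    }
    if (length(n1_markers) == 0L || length(n2_markers) == 0L) {
      abort("gradient needs non-empty n1_markers and n2_markers")
    }
    if (length(intersect(n1_markers, n2_markers)) > 0L) {
      abort("n1_markers and n2_markers overlap; planted gene sets must be disjoint")
    }
  }

  if (!is.null(lr_truth)) {
    lr_truth <- as_tibble(lr_truth)
    need <- c("ligand", "receptor", "sender", "receiver", "pattern")
    if (!all(need %in% names(lr_truth))) {
      abort("`lr_truth` needs columns ligand, receptor, sender, receiver, pattern")
    }
    bad <- setdiff(unique(c(lr_truth$sender, lr_truth$receiver)), cl_names)
    if (length(bad)) abort(sprintf("lr_truth references unknown clusters: %s", toString(bad)))
    if (!all(lr_truth$pattern %in% c("shared", "gained", "lost"))) {
      abort("lr_truth pattern must be shared / gained / lost")
    }
  }
  if (!is.null(condition_de)) {
    condition_de <- as_tibble(condition_de)
    need <- c("gene", "cluster", "condition", "log2fc")
    if (!all(need %in% names(condition_de))) {
      abort("`condition_de` needs columns gene, cluster, condition, log2fc")
    }
    if (!all(condition_de$condition %in% conditions)) abort("condition_de: unknown condition")
    if (!all(condition_de$cluster %in% cl_names)) abort("condition_de: unknown cluster")
  }
  if (n_modules > 0) {
    if (module_size < 2) abort("`module_size` must be >= 2")
    if (!is.null(module_condition) && length(module_condition) != n_modules) {
      abort("`module_condition` must have one entry (or NA) per module")
    }
    if (!is.null(module_gradient)) {
      if (length(module_gradient) != n_modules) {
        abort("`module_gradient` must have one logical per module")
      }
      if (any(module_gradient) && is.null(gradient_cluster)) {
        abort("a gradient-coupled module needs a gradient_cluster")
      }
    }
  }

  cfg <- list(
    n_genes = as.integer(n_genes), n_cells = n_cells, clusters = clusters,
    conditions = conditions, baseline_mean = baseline_mean,
    dispersion = dispersion, marker_log2fc = marker_log2fc,
    marker_base_factor = marker_base_factor,
    polarity_base_factor = polarity_base_factor,
    condition_de = condition_de,
    n_modules = as.integer(n_modules), module_size = as.integer(module_size),
    module_factor_sd = module_factor_sd, module_base_mean = module_base_mean,
    module_condition = module_condition,
    module_condition_shift = module_condition_shift,
    module_gradient = module_gradient,
    gradient_cluster = gradient_cluster, n1_markers = n1_markers,
    n2_markers = n2_markers, gradient_log2fc = gradient_log2fc,
    lr_truth = lr_truth, lr_log2fc = lr_log2fc,
    lowq_fraction = lowq_fraction,
    n_housekeeping = as.integer(n_housekeeping),
    housekeeping_mean_factor = housekeeping_mean_factor,
    mito_prefix = mito_prefix,
    mito_mean_factor = mito_mean_factor, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"

  # gene universe must fit
  named <- sim_named_genes(cfg)
  reserved <- n_modules * module_size + length(mouse_mito_genes) + n_housekeeping
  if (n_genes < length(named) + reserved + 10) {
    abort(sprintf("n_genes = %d too small: %d planted + %d reserved genes need headroom",
                  n_genes, length(named), reserved))
  }
  if (any(startsWith(named, mito_prefix))) {
    abort(sprintf("planted gene symbols must not use the mitochondrial prefix '%s'", mito_prefix))
  }
  cfg
}

# all explicitly named planted genes (symbol sharing across roles is allowed)
sim_named_genes <- function(cfg) {
  unique(c(
    unlist(map(cfg$clusters, "markers")),
    if (!is.null(cfg$gradient_cluster)) c(cfg$n1_markers, cfg$n2_markers),
    if (!is.null(cfg$lr_truth)) c(cfg$lr_truth$ligand, cfg$lr_truth$receptor),
    if (!is.null(cfg$condition_de)) cfg$condition_de$gene
  ))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d genes, %s cells (%s), %d clusters, seed %d\n",
              x$n_genes, paste(x$n_cells, collapse = "+"),
              paste(x$conditions, collapse = "/"), length(x$clusters), x$seed))
  invisible(x)
}
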