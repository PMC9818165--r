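---
title: "Methods: characterising a pre-metastatic niche from two-condition scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterising a pre-metastatic niche from two-condition scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmniche)
```

# The analysis problem

A growing primary tumor conditions distant organs — most prominently the
lung — before any metastatic cell arrives, recruiting immunosuppressive
myeloid cells and remodelling the vasculature. pmniche implements the
computational core of a two-condition single-cell RNA-seq comparison of
such a niche (wild-type vs tumor-bearing animals): quality control and
normalization, signature-gene calling, marker-based annotation and
composition shifts, N1/N2 neutrophil polarization analysis, co-expression
module detection, and differential ligand-receptor networks.

Because studies of this kind often leave the underlying count matrices
undeposited, the package treats a *synthetic world with planted ground
truth* as a first-class citizen: every inference stage is exercised, and
its operating characteristics measured, against data whose true markers,
gradients, modules and interactions are known exactly.

# The synthetic world

`sim_config()` / `simulate_counts()` draw counts gene-by-cell from a
negative binomial with mean/inverse-dispersion parameterisation,
`Var = mu + mu^2 / theta`. Defaults and the reasoning behind them:

* **Dispersion `theta = 10`** — typical droplet scRNA-seq overdispersion;
  shared across genes for simplicity. The source study reports no
  distributional model of its data, so NB with shared dispersion is this
  package's modelling choice, not a reconstruction.
* **Baseline mean 0.2** with per-gene log-normal spread (sd 0.5 on the log
  scale) — a sparse matrix with ~18% detection per background gene.
* **Cell numbers `c(WT = 1200, TB = 1000)`** — a desk-scale version of a
  two-sample lung dataset (the original tissue atlases profiled roughly
  12,700 and 10,000 cells); the ratio is preserved, the scale is chosen so
  the full pipeline runs in seconds.
* **Ten clusters** mirroring a mouse lung map, each defined by the marker
  conventionally used for it (Cd79a B cells, Cd3e T cells, Ncr1 NK,
  Cd3e+Klrb1c NKT, Csf1r monocytes, Mrc1 macrophages, Cd209a DCs,
  Cxcr2+Ly6g neutrophils, Pecam1+Cdh5 endothelium, Prox1 lymphatic
  endothelium). Marker elevation is `marker_log2fc = 2.5` log2 units in
  the marker's cluster. The tumor-bearing condition expands neutrophils
  (5% to 20%) and classical monocytes (10% to 15%), the hallmark myeloid
  influx of the niche.
* **Expression tiers.** Cluster markers and planted condition-contrast
  genes get a deterministic baseline of `3 x` the background scale
  (well-expressed markers); N1/N2 polarity genes get `25 x` — granule
  transcripts of the S100a8/a9 class are among the most abundant mRNAs in
  neutrophils, and the polarization score averages only eight genes, so
  their depth matters; 50 housekeeping genes at `100 x` give every
  library a realistic high-expression backbone so that no planted block
  dominates the per-cell total; 13 mitochondrial genes (named with the
  mouse `mt-` symbols) at `40 x` put a healthy cell near 3-4%
  mitochondrial content.
* **Polarization gradient.** Cells of the gradient cluster receive a
  latent `t ~ Uniform(0, 1)`; N2-marker means scale as `2^(g t)` and
  N1-marker means as `2^(-g t)` with `g = 2`, keeping the effect
  interpretable in log2-fold-change units. `t` lives only in the truth
  manifest and is never passed to inference.
* **Modules.** Each planted module's genes share a per-cell log-normal
  factor `exp(N(0, 0.5))`, at base mean 5 (moderately expressed genes). A
  condition-linked module shifts its factor by 0.5 log2 units in its
  condition. We deliberately keep this shift moderate: because
  library-size normalization divides by the per-cell total, a module
  whose activation materially inflates the library couples (negatively)
  to every other gene, which both distorts recovery and is biologically
  implausible for a 50-gene program. An optional gradient-coupled module
  adds `g log(2) (t - 1/2)` to the factor of gradient-cluster cells,
  emulating a co-expression program tied to the N1-to-N2 transition.
* **Ligand-receptor truth.** Planted pairs elevate the ligand in the
  sender cluster and the receptor in the receiver cluster by
  `lr_log2fc = 4` log2 units, under the stated condition pattern
  (`gained` = tumor-bearing only, `lost` = wild-type only, `shared` =
  both). At the default baseline this puts on-state detection near 0.9
  and off-state near 0.18, straddling the 50% calling threshold with wide
  margins. The default truth uses axes reported for the lung niche
  (S100a6-Anxa2, Cfh-Itgam, Serpine2-Plaur gained; Icam1-Itgav,
  Lrg1-Acvrl1 lost).
* **Low-quality cells** (5% by default) are *constructed* to fail QC:
  their counts are drawn on a fixed subset of 137 genes (so fewer than
  200 detected) and their mitochondrial counts are topped up to about a
  third of the cell total (so above 20%). This makes the QC filter's
  sensitivity and specificity exactly checkable.
* **Reproducibility.** One RNG stream, seeded once; draws are made in a
  fixed order (baselines, gradient, module factors, the count matrix in
  one vectorised call, then low-quality cells), so a config plus seed
  reproduces the written `.mtx` byte for byte.

What the generator does *not* model: ambient RNA, doublets, batch
effects, UMI/read-level noise, sequencing errors. A green recovery test
therefore establishes correctness of the *inference logic* under an
idealised noise model, not robustness to artefacts that real data carry.

# Quality control and normalization

`compute_qc()` counts detected genes (nFeature) and the mitochondrial
percentage per cell (prefix-matched gene symbols, case-insensitive, so
mouse `mt-` and human `MT-` both work). Removal thresholds follow the
conventional filter — fewer than 200 or more than 3,000 detected genes,
or more than 20% mitochondrial content — and are applied as *strict*
inequalities, so boundary cells are retained. A zero-count cell fails
with reason `"empty"` rather than dividing by zero. `log_normalize()` is
the standard library-size transform `ln(1 + 10,000 c / total)`; zeros map
to zeros and the result is invariant to scaling a cell's counts. The
feature floor of 200 presumes a transcriptome-scale gene universe; on
reduced simulated panels (hundreds of genes) the floor should be scaled
down, as the package's own tests do.

# Signature genes

`call_signatures()` implements the dual criterion: a gene must be
detected (raw count > 0) in **more than 50%** of the cells of at least
one group *and* differ by **more than 1 log2 unit** (2-fold). Decisions
the criterion's prose leaves open, fixed here and configurable:

* fold change is computed on de-logged normalized means
  (`mean(expm1(value))`) with pseudocount 1 — the convention of the
  standard toolkit the transform comes from;
* "expressed" means detection, not a normalized-value threshold;
* both inequalities are strict, exactly as printed;
* no hypothesis test enters the call — the criterion is purely
  fraction + fold change; a rank-sum p-value can be annotated
  (`rank_test = TRUE`) but never drives `called`.

# Annotation and composition

`annotate_clusters()` works at cluster level: panel-gene means per
cluster are z-scored across clusters, each cell type scores as the mean z
of its markers, and the argmax wins (ties broken by panel order). This is
a defined, testable stand-in for "annotated based on established
markers" narratives; per-cell reference classifiers are out of scope.
`composition_shift()` reports counts, within-condition proportions and
log2 proportion ratios, with a Haldane-style pseudo-proportion
`1/(2N)` for clusters empty in one condition (flagged in the output).

# Polarization, pseudotime and the association screen

The N1 (anti-tumor) to N2 (pro-tumor) neutrophil axis is scored per cell
as `mean(z of N2 markers) - mean(z of N1 markers)` (defaults: N2
Mmp9/S100a8/S100a9/Arg1; N1 Ccl3/Fas/Cxcl3/Tnf). `pseudotime_rank()`
maps the score to `t = rank/(n-1)`. This deliberately replaces a learned
trajectory embedding: the downstream deliverable is the set of
gene-pseudotime associations, which a fully specified rank ordering
supports while remaining exactly testable. Fidelity to any particular
trajectory algorithm is a non-goal.

`screen_pseudotime_genes()` uses Spearman correlation (robust to the
log-scale count distribution), a t-approximation for p-values, and
Benjamini-Hochberg correction computed **only over tested genes**
(detection at least 5%), so undetectable genes cannot dilute the q-values.
Association calls need both `|rho| > 0.3` and `q <= 0.05`; both knobs are
package choices, configurable. `hub_genes()` intersects the called genes
with named modules — the trajectory x co-expression intersection used to
nominate transition-driving genes.

# Co-expression modules

`detect_modules()` is a lightweight, fully specified take on weighted
co-expression analysis: top-variance genes, adjacency `|cor|^beta`,
average-linkage clustering of `1 - adjacency`, a *static* cut at 0.995 of
the maximum merge height, minimum module size 30, eigengene = first PC of
the gene-standardized submatrix (unit variance, sign-oriented so the mean
gene-eigengene correlation is positive), and iterative merging of
modules whose eigengenes correlate above 0.9. Deliberate divergences
from the reference tooling: no topological-overlap transform, no dynamic
tree cut, no metacell machinery — planted-module recovery does not need
them and every remaining step is exactly specified. A lightweight
k-nearest-neighbour pooling step (`pool = TRUE`, `pool_k = 10`) is
available for noisy inputs in the spirit of metacell aggregation.

Two practical notes, both visible in the tests. First, the soft power:
the textbook default (smallest beta in 1..12 reaching scale-free fit
R^2 >= 0.8, else 6) is implemented, but per-cell correlations are much
weaker than the bulk-level correlations that rule was designed for; with
within-module correlations around 0.25-0.35, `beta = 3` keeps planted
co-expression above the static cut while pushing background adjacency to
zero, and is what the package's pipeline and tests use. Second,
top-variance gene selection on log-normalized values favours low-detection
genes (their values are near-Bernoulli); when the gene universe is small
enough, entering all genes into the network sidesteps the bias.

`module_trait_correlation()` reports signed Pearson correlations of each
eigengene with condition or cluster indicators plus two-sided p-values,
so "module X is positively correlated with trait Y" claims are
machine-checkable.

# Ligand-receptor networks

`merge_lr_databases()` unions curated pair lists (deduplicated,
case-normalized, source-tagged, deterministically ordered).
`expression_fractions()` computes per-cluster detection fractions, and
`call_interactions()` emits an edge for every ordered cluster pair whose
ligand and receptor are both detected in **at least 50%** of the
respective cluster's cells — note the inclusive threshold here versus the
strict one in signature calling; each follows its own criterion as
printed. Threshold comparisons are done in exact rational arithmetic so
a gene detected in exactly half the cells passes. The two criteria of the
underlying rule are interpreted as ligand-in-sender AND
receptor-in-receiver at the same threshold. `differential_network()`
labels edges shared/gained/lost between conditions; the conservation
identity `|gained| + |lost| + 2|shared| = |edges_A| + |edges_B|` and
monotonicity in the threshold are tested properties.

# Orchestration and provenance

`run_pipeline()` chains simulate, qc, annotate, composition, signatures,
polarize, modules and lrnet, halting with a stage-named error when an
upstream output is missing. Every output table starts with a
`# stage=<name> params=<hash>` provenance line, a resolved copy of the
configuration is written next to the outputs, and a rerun with the same
configuration and seed is byte-identical. The package deliberately
exposes this as an R function plus per-stage functions rather than a
shell tool; `scripts/acceptance.R` shows the headless invocation.

# Numerical and degenerate-input choices

* QC: zero-total cells fail with a named reason; never division by zero.
* Normalization refuses zero-total cells (they should have been filtered).
* Pseudotime of constant scores returns 0.5 everywhere with a warning;
  fewer than three cells is an error; fewer than ten cells refuses the
  correlation screen.
* Spearman p-values use the t approximation, appropriate at the screen's
  minimum n of 10 and standard far above it.
* Constant traits yield `NA` correlations with a warning, not an error.
* Composition ratios for empty clusters use the Haldane pseudo-proportion
  and are flagged rather than silently clamped.
* Ties: annotation argmax breaks by panel declaration order; signature
  ordering breaks |log2fc| ties lexicographically by gene id — both
  deterministic.

# Known limitations

* The NB world is idealised; no artefact models (see above), so recovery
  rates here are upper bounds on real-data performance.
* The static tree cut assumes modules separate at a global height; deeply
  nested co-expression structure would need the dynamic cut this package
  deliberately omits.
* The marker-axis pseudotime is one-dimensional by construction; branching
  trajectories are out of scope.
* Cluster labels are inputs (ground truth in simulation, upstream
  clustering on real data); the package neither clusters nor integrates
  batches.
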