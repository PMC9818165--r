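Package: pmniche
Title: Two-Condition Single-Cell Analysis of the Lung Pre-Metastatic Niche
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for characterising a pre-metastatic
    niche from two-condition single-cell RNA-seq count data: cell-level
    quality control and log-normalization, dual-criterion signature-gene
    calling (detection fraction and fold change), marker-based cluster
    annotation and condition composition shifts, N1/N2 neutrophil
    polarization scoring with a marker-axis pseudotime and a
    rank-correlation gene screen, lightweight WGCNA-style co-expression
    module detection with module eigengenes and module-trait correlation,
    and differential ligand-receptor interaction networks between
    conditions. Ships a negative-binomial synthetic-data generator with
    planted ground truth (marker genes, abundance shifts, a polarization
    gradient, co-expression modules, condition-specific ligand-receptor
    edges, and low-quality cells) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
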