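Package: tmescope
Title: Tumor-Microenvironment Interaction, CNV and Heterogeneity Analysis for Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-styled toolkit for dissecting the tumor
    microenvironment from single-cell UMI count data: quality-control
    filtering and barnyard multiplet-rate estimation, marker-panel cell-type
    annotation, immune-checkpoint interaction scoring with a
    ratio-preserving permutation null, pan-ligand-receptor interactome
    scoring aggregated by one-sided Wilcoxon signed-rank tests with Storey
    q-value FDR control, expression-inferred copy-number profiling by
    chromosome-ordered moving averages against a diploid reference, stem-cell
    marker-panel tumor stratification, and per-sample immune-composition
    correlation. Ships a seeded negative-binomial simulator that plants cell
    types, checkpoint axes, CNV segments and multiplets as ground truth for
    every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
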