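Package: tppshift
Title: Thermal Proteome Profiling Melting-Curve Analysis and Target
    Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of thermal proteome profiling (TPP) experiments for
    drug-target deconvolution. Fits three-parameter sigmoid melting curves
    to temperature-gradient relative-abundance profiles, estimates melting
    temperatures (Tm) and treatment-induced shifts (delta Tm), and tests
    for ligand-stabilised proteins by comparing pooled against
    per-condition curve fits with an F-statistic (the NPARC approach) under
    Benjamini-Hochberg false-discovery-rate control. Includes a synthetic
    TPP data generator with known ground truth, a monoisotopic-mass and
    adduct m/z calculator for validating compound identifications by ppm
    error, mass-spectrometry component-table filters with cross-polarity
    deduplication, and evidence-integration helpers (target-list merging,
    interaction-network degree ranking, docking-score thresholds).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
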