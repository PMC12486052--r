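Package: dvcforest
Title: Causal-Forest Derivation of Dose-Volume Constraints and Empirical Proton RBE
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving mandible dose-volume constraints (DVCs) for
    osteoradionecrosis from observational photon (VMAT) and proton (PBSPT)
    cohorts with causal machine learning. Implements propensity-score 1:1
    optimal matching with balance diagnostics, worst-case standardized mean
    difference (SMD) checks of within-group confounding, an honest causal
    forest with out-of-bag conditional treatment effects and doubly-robust
    (AIPW) average treatment effect estimation, a percentile threshold scan
    that selects the ATE-maximizing dose-volume cutoff with bootstrap
    confidence intervals, and conversion of paired photon/proton tolerance
    curves into empirical relative biological effectiveness (RBE) values by
    equivalent-constraint-dose interpolation. A seeded synthetic cohort
    generator with known ground-truth effects supports testing and power
    studies without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
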