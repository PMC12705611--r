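Package: phenoloop
Title: Closed-Loop Dose-Response Phenotyping Analysis for Automated Plant
    Growth Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing automated dose-stress plant phenotyping
    experiments run in fabricated-ecosystem growth chambers. Simulates
    virtual experiments with dose-dependent logistic growth and imaging
    noise, computes hyperspectral phenotype metrics (a minimum-corrected
    NDVI, dictionary-based shoot health fractions, multi-view size proxies),
    fits Gaussian-process dose-response models with an ARD kernel and
    constant noise, proposes new doses by variance-based Bayesian
    optimisation, evaluates models with stratified repeated cross-validation
    (NRMSE, CRPS, bootstrap intervals, scrambled-target null ratios), and
    runs daily time-series analytics: Savitzky-Golay smoothing with spline
    interpolation, per-day dose correlations and Tukey screens against the
    untreated control, and UMAP/HDBSCAN trajectory clustering.
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
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    uwot,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
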