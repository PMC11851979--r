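Package: mssrnn
Title: Minimum Sample Size Requirements for Neural Networks on Likert Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Monte Carlo framework for estimating the minimum sample size
    requirement (MSSR) when fitting feed-forward neural networks to ordinal
    (Likert-scale) predictors. Simulates datasets from a registry of nine
    nonlinear data-generating formulas over a 108-cell condition grid,
    Likertizes latent normal predictors, fits grid-searched multilayer
    perceptrons with Adam optimisation and early stopping, and decides the
    MSSR under two criteria: stability of test-set R-squared relative to the
    theoretical maximum explainable variance, and outperformance of a linear
    regression benchmark. Includes a semi-analytic population R-squared
    oracle based on truncated-normal moments, decision replay on reference
    summary tables, and a Spearman rank-correlation meta-analysis of MSSR
    against the design factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
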