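Package: lscom
Title: Longitudinal Multilevel CFA-MTMM Models for Interchangeable and
    Structurally Different Raters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Specification, simulation, and two-level maximum-likelihood
    estimation of latent-state combination-of-methods (LS-COM) models for
    longitudinal multitrait-multimethod measurement designs that mix
    structurally different methods (e.g., self- and parent reports) with a
    set of interchangeable raters (e.g., multiple peers) nested within
    targets.  Provides declarative model templates with
    measurement-invariance and correlation-policy constraints, model-implied
    two-level moment structures, consistency, method-specificity and
    reliability variance-component coefficients, a population-parameter
    generator working from target variance shares, a full-information
    two-level Gaussian maximum-likelihood estimator with standard errors,
    chi-square fit and improper-solution diagnostics, and a Monte-Carlo
    harness computing aggregated parameter and standard-error bias
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
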