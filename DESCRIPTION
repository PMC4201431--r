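Package: dynmix
Title: Dynamic N-Mixture Models for Repeated Counts in Before-After
    Control-Impact Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maximum-likelihood estimation of abundance, recruitment,
    apparent survival and detection probability of unmarked animals from
    repeated count data collected under a robust design (primary seasons
    containing secondary visits), with Poisson or zero-inflated Poisson
    latent abundance, covariates on every parameter, AICc multi-model
    inference with model-averaged estimates and unconditional standard
    errors, and a parametric-bootstrap goodness-of-fit test. Includes
    the comparison estimators practitioners reach for alongside count
    models: the Huggins closed-population conditional-likelihood
    estimator with Horvitz-Thompson abundance, Cormack-Jolly-Seber
    apparent survival with unequal inter-occasion intervals, and a
    Poisson random-intercept mixed model fitted by the Laplace
    approximation. A synthetic-data generator reproduces the structure
    of a two-season before-after control-impact (BACI) trapping study so
    every estimator can be exercised and validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
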