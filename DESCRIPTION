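Package: tvcox
Title: Time-Varying Covariate Effects in the Cox Non-Proportional Hazards Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and inference for time-varying covariate effects in
    right-censored survival data. Log hazard-ratio trajectories beta(t) are
    spanned by B-spline bases and estimated by proximal Newton maximization of
    the (optionally penalized) log-partial likelihood, with Breslow handling of
    tied event times and stratified baseline hazards. Includes P-spline
    (discrete difference) and smoothing-spline (integrated squared derivative)
    penalties, tuning-parameter selection by information criteria (mAIC, TIC,
    GIC) and cross-validated partial likelihood, Wald tests of the proportional
    hazards assumption, zero-effect and pointwise tests, pointwise confidence
    bands, Breslow baseline hazard and survival prediction, a simulator for
    survival data with known time-varying effects, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    splines,
    stats,
    utils,
    MASS,
    pracma,
    jsonlite,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
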