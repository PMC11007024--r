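Package: tvvardyn
Title: Time-Varying Vector Autoregression for Dyadic Affect Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of time-varying lag-1 vector autoregressive (TV-VAR)
    models for couples' daily diary affect data via penalized varying-coefficient
    B-splines with generalized cross-validation smoothing selection, per-smooth
    effective degrees of freedom and approximate significance tests. Reduces each
    dyad's fitted coefficient trajectories to means and standard deviations over
    time, flags time-varying dynamic parameters, and relates the summaries to
    relationship quality and dissolution through deterministic bidirectional
    stepwise linear and logistic regression. Includes a synthetic dyadic diary
    generator with known ground truth for calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    splines,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
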