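Package: sncpt
Title: Self-Normalized Change-Point Detection for ARMA Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects a single structural break in the parameters of a
    stationary ARMA(p,q) time series with a self-normalized CUSUM test on
    recursively computed model residuals. The test statistic standardizes
    segment mean differences by within-segment partial-sum processes, so no
    long-run variance estimation or bandwidth choice is needed. Includes
    Gaussian quasi-maximum-likelihood fitting with recursive residual
    extraction, an optional support-vector-regression residual backend,
    Monte Carlo critical values from both finite-sample null simulation and
    the Brownian-bridge limit functional, a change-point location estimator,
    two benchmark score-type tests, a seeded synthetic generator for ARMA
    series with a single break, and a size/power simulation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
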