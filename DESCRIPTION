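Package: rainmob
Title: Rainfall Anomalies and Short-Term Human Mobility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking gridded precipitation data to georeferenced
    household-survey clusters and estimating the association between rainfall
    anomalies and short-term human mobility. Implements the empirical-percentile
    rainfall deviation (the 12-month pre-interview rainfall sum ranked against
    the same window over the 29 previous years), restricted-cubic-spline
    logistic regression with country fixed effects and cluster-robust sandwich
    variance, marginal standardization (g-computation) risk ratios at drought,
    median and heavy-rain percentiles with delta-method or cluster-bootstrap
    intervals, and a joint Wald test for effect modification by marital status.
    Ships a fully parameterized synthetic data generator (seasonal rainfall
    grid, multi-country survey, U-shaped outcome model with site-level
    heterogeneity) plus a Monte-Carlo oracle for the true marginal risk
    ratios, so the whole pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
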