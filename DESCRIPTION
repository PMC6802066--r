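Package: occutrend
Title: Bayesian Multi-Season Occupancy Models for Regional Trend Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits autoregressive (autologistic) multi-season occupancy models
    to detection/nondetection survey data with imperfect detection, the model
    family used by grid-based regional bat monitoring programs. Provides
    derived dynamic parameters (persistence, colonization, the recursive
    occupancy trajectory, and the occurrence growth rate used as a trend
    metric), vague and empirically informed Normal priors with
    posterior-to-prior updating across monitoring periods, a blocked Gibbs
    sampler with Polya-Gamma augmentation, split-chain Gelman-Rubin
    diagnostics, posterior AUC predictive summaries, Moran's I residual
    spatial autocorrelation profiles, prior-sensitivity comparison, and a
    synthetic survey-data generator with spatially balanced site selection
    and known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    coda,
    rjags,
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
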