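Package: rimcorrect
Title: Original-Scale Predictions from Log-Scale Random-Intercept and
    Linear Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fits heteroscedastic random-intercept models to
    log-transformed positive responses and computes corrected
    predictions on the original scale. Exponentiating a fitted
    log-scale value underestimates the conditional mean of a
    log-normal response; this package provides the multiplicative
    correction factors for the error term and for the random
    intercept (marginal, best-linear-predictor, conditional-variance
    and smearing variants), their generalization to arbitrary linear
    mixed models via the conditional covariance of the random
    effects, a Monte-Carlo back-transformation for transformations
    other than the logarithm, synthetic-data generators for
    log-normal and gamma clustered designs, and a replication harness
    summarising mean squared prediction error across methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    nlme,
    withr,
    jsonlite
Config/testthat/edition: 3
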