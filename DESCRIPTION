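Package: egmr
Title: Fractional-Order Grey Prediction Models for Small-Sample Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grey prediction models for short, nonnegative time series
    (10-30 points), built around the even grey model with fractional-order
    accumulation EGM(1,1,r). Provides the fractional accumulation generation
    operator (r-AGO) and its inverse, least-squares estimation of the grey
    difference equation, selection of the accumulation order r by particle
    swarm optimization or grid search of the mean relative simulation error,
    the classic GM(1,1) and discrete DGM(1,1) baselines, quasi-smoothness
    modeling-condition diagnostics, a synthetic-series generator for
    parameter-recovery studies, and a small command-line interface. Ships
    the China beef-consumption case study (1991-2015 with 2016-2018 holdout)
    as a packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
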