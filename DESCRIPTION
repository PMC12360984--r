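Package: msdwork
Title: Prognostic Models for Work Absence and Presenteeism in
    Musculoskeletal Primary Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Development and internal-external cross-validation (IECV) of
    risk-prediction models for work absence and presenteeism from
    multi-study individual participant data (IPD) of adults consulting
    primary care with musculoskeletal disorders.  Provides a synthetic
    multi-study IPD generator with sporadic and systematically missing
    predictors, multilevel joint-model multiple imputation by a
    latent-normal Gibbs sampler, multilevel mixed-effects model
    development with fractional-polynomial form checks and Van
    Houwelingen-le Cessie heuristic shrinkage, validation statistics
    (C-statistic, calibration slope, calibration-in-the-large, O/E ratio,
    smooth calibration curves) with Rubin's-rules pooling,
    leave-one-study-out IECV with random-effects meta-analysis of
    performance, Riley minimum sample-size criteria, and frozen scorers
    for the three published coefficient sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    metafor,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
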