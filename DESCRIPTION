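Package: improvebleed
Title: External Validation and Recalibration of the IMPROVE Bleeding Risk Score
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating and updating additive clinical
    risk scores, instantiated on the IMPROVE (International Medical Prevention
    Registry on Venous Thromboembolism) bleeding risk assessment model for
    acutely ill hospitalized medical patients. Scores admissions from raw
    predictors (including the Japanese eGFR equation), stratifies risk into
    the 11-group and two-group schemes, and quantifies predictive performance:
    two-risk-group diagnostic accuracy with exact confidence intervals,
    Kaplan-Meier 14-day cumulative incidence, cluster-robust odds ratios,
    empirical and binormal maximum-likelihood ROC analysis over ordinal risk
    groups, and calibration (expected/observed ratio, calibration-in-the-large,
    calibration slope, loess calibration curves). Missing laboratory predictors
    are handled by chained-equation multiple imputation with predictive mean
    matching and Rubin's-rules pooling on the appropriate scales, and the model
    is updated by logistic recalibration. A synthetic-cohort generator with
    known latent risk provides a fully reproducible test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    sandwich,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
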