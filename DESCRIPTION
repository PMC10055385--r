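Package: tpmrisk
Title: Temporal Phenomic Maps and Convolutional Risk Prediction for
    Psoriatic Arthritis from Claims Data
Version: 0.1.0
Authors@R:
    person("tpmrisk", "maintainers", email = "tpmrisk@example.org",
           role = c("aut", "cre"))
Description: Builds case-control cohorts of psoriasis patients from
    longitudinal claims data, encodes each patient's observation window as a
    normalized temporal phenomic map (diagnosis and drug codes by week), and
    trains a small convolutional neural network to predict new-onset
    psoriatic arthritis half a year ahead. Includes a seeded synthetic-claims
    generator with planted ground truth, cross-validated evaluation with ROC
    threshold selection, occlusion-sensitivity feature importance, and
    logistic-regression odds ratios for identified predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
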