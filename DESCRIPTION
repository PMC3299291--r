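Package: mrtdqspr
Title: QSPR Models for Maximum Recommended Therapeutic Dose of Antiretrovirals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts the maximum recommended therapeutic dose (MRTD,
    mg/kg/day) of antiretroviral drugs from six molecular property
    descriptors. Ships the reference multiple linear regression equation and
    the reference 6-2-1 feedforward neural network for a 31-compound
    antiretroviral dataset (bundled), together with a from-scratch ordinary
    least squares refitter with coefficient inference, an online
    backpropagation trainer for 6-H-1 networks with min-max target scaling,
    and model-comparison statistics: RMSE, Kendall rank correlation with
    exact small-sample p-values, and Bland-Altman limits of agreement. A
    seeded synthetic-data generator with known ground-truth models supports
    property testing, and a command-line interface exposes the full
    predict/fit/train/validate workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
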