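Package: measureval
Title: Predictor Measurement Heterogeneity and Out-of-Sample Performance
    of Clinical Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation framework for studying how heterogeneity in
    predictor measurement between model derivation and external validation
    affects the out-of-sample performance of logistic prediction models.
    Implements a taxonomy of measurement error models (random, systematic,
    differential) linking exact and pragmatic predictor measurements,
    analytic performance expressions (binormal c-statistic approximation,
    Spiegelhalter decomposition of the Brier score), logistic recalibration
    (calibration slope and calibration-in-the-large), and a full-factorial
    Monte Carlo scenario engine for derivation-to-validation model
    transport, together with large-sample transport experiments,
    configuration-driven batch runs and report rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    MASS,
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
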