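Package: predictval
Title: External Validation of PREDICT-Style Breast Cancer Prognostic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes prognostic index, competing-risk survival composition and
    treatment effects for PREDICT-style early breast cancer prognostic models
    from a versioned coefficient configuration, and runs a full external
    validation: Kaplan-Meier and Cox survival analysis, Royston D prognostic
    separation, fixed-horizon ROC/AUC, median-split survival curves,
    predicted-versus-observed calibration tables, and the Integrated
    Calibration Index with restricted-cubic-spline smoothed calibration
    curves. Includes a synthetic-cohort generator that draws covariates with
    realistic marginal structure and event times from the engine's own
    competing-risk model, so every validation stage can be tested against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    survival,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
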