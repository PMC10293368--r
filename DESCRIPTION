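Package: hipmort
Title: External Validation of Hip Fracture Mortality Risk Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for external validation of three prognostic models for
    mortality after hip fracture surgery: the Nottingham Hip Fracture Score
    (NHFS), the Scottish-audit model of Holt and colleagues, and the Hip
    fracture Estimator of Mortality Amsterdam (HEMA). Provides the exact
    scoring tables and logistic risk equations of the three models,
    risk-group classification, horizon-specific mortality labelling from
    follow-up dates, Kaplan-Meier survival by risk group, and a validation
    battery computed from first principles: rank-based AUC with DeLong
    confidence intervals and paired DeLong model comparison,
    Hosmer-Lemeshow calibration, and positive/negative predictive values.
    A synthetic cohort generator reproduces the covariate prevalences and
    mortality structure of a typical elderly hip-fracture population so the
    whole pipeline can be exercised and tested without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
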