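Package: mewseval
Title: Evaluation of the Modified Early Warning Score as a Mortality Predictor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the Modified Early Warning Score (MEWS) as a
    prognostic marker for in-hospital mortality after unplanned escalation of
    care. Reconstructs a per-patient cohort exactly from a cumulative
    threshold cross-classification table (and the reverse), computes MEWS
    from raw bedside vitals via a configurable banded scoring table, fits the
    univariable logistic model of death on score by its own Newton-Raphson
    maximum-likelihood routine, performs threshold scans with Youden-type
    cut-point selection, produces the complete 2x2 diagnostic-accuracy metric
    ledger (sensitivity, specificity, predictive values, likelihood ratios,
    odds and risk ratios, kappa, Youden J, numbers needed to
    diagnose/misdiagnose, misclassification) with 95% confidence intervals,
    and internally validates the whole-model statistic by a seeded
    nonparametric bootstrap. A synthetic-cohort generator with a categorical
    score distribution and logistic mortality link makes every stage testable
    without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
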