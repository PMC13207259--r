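Package: tedclaims
Title: Validation of Claims-Based Thyroid Eye Disease Phenotyping Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to validate rule-based and machine-learning claims
    phenotyping algorithms for thyroid eye disease (TED) against an
    imperfect note-derived reference standard. Provides a seedable
    generator for synthetic linked claims/registry cohorts, cohort
    inclusion and enrollment logic, six declarative code-based
    identification algorithms with temporal co-occurrence windows, a
    full diagnostic-accuracy toolkit (sensitivity, specificity,
    likelihood ratios, prevalence-transported predictive values, AUC,
    threshold sweeps, confidence intervals), and a recursive
    feature-elimination consensus pipeline over gradient-boosted tree
    models. Numbered analysis scripts reproduce the validation workflow
    end to end on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    tibble,
    jsonlite,
    Matrix,
    methods,
    xgboost,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
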