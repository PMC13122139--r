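Package: dhdrisk
Title: Risk Prediction, Fairness Auditing and Explainability for Delayed
    Hospital Discharge
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and responsibly evaluating clinical risk
    models for delayed hospital discharge (alternate level of care) among
    older adults. Provides a synthetic admission-cohort generator with a
    known logistic ground truth, look-back feature construction and
    patient-level data splitting, logistic-regression and gradient-boosted
    risk models with grouped cross-validated tuning, Platt scaling (global
    and group-stratified) with Brier/ECE/intercept/slope diagnostics,
    threshold-free fairness audits (AUC, cross-group xAUC and ECE parity
    ratios), decision-curve analysis, model-agnostic explainability
    (permutation importance, partial dependence, Shapley, breakdown,
    ceteris paribus), and PCA-based clustering of explanation summaries
    over high-risk patients.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
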