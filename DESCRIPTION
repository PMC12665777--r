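Package: qsarkit
Title: QSAR Modelling Pipeline with Genetic-Algorithm Feature Selection,
    Applicability-Domain Assessment and Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end quantitative structure-activity relationship (QSAR)
    modelling for small congeneric inhibitor series: descriptor ingestion and
    pIC50 conversion, preprocessing (standardization, correlation and variance
    filtering, stratified splitting), descriptor-subset selection by binary
    genetic algorithm with a complexity-penalized adjusted R-squared fitness
    (plus stepwise-AIC, VIF and BIC alternatives), multiple linear regression
    and partial least squares model fitting with optional tree-ensemble
    baselines, a validation battery (repeated k-fold cross-validation,
    Y-randomization, leave-cluster-out, split conformal prediction),
    dual applicability-domain assessment (Mahalanobis distance with a
    chi-squared threshold, and Williams leverage), linear-model
    interpretability (permutation importance, exact additive attribution),
    and virtual-screening hit triage. Ships a published eight-descriptor
    KRAS inhibitor GA-MLR equation as a built-in reference model and a
    synthetic-data generator emulating the statistical structure of a
    62-compound descriptor table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    xgboost,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
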