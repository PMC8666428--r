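Package: rpscore
Title: Blood-Based Response Prediction Score Derivation for Preoperative
    Chemoradiotherapy in Rectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives and evaluates a compact linear Response Prediction
    Score for pathologic response to preoperative chemoradiotherapy in
    locally advanced rectal cancer from clinical features and
    early-treatment blood panels. Provides a synthetic cohort generator
    with planted hematologic effects, Kennard-Stone and
    Morais-Lima-Martin representative data splitting, a repeated
    benchmark of six model families with tuning-set hyperparameter
    search and univariate feature selection, generalized across-repeat
    coefficient importance, significance-curve score-size selection,
    inflammatory and nutritional indicator baselines (NLR, PLR, LMR,
    PNI), ROC and precision-recall evaluation, and quartile
    stratification of response and downstaging outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    nnet,
    ranger,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
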