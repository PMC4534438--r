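Package: PulmoScreen
Title: Ensemble Questionnaire Classification for Paediatric Chronic Cough
    Diagnosis Support
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Questionnaire-based diagnostic decision support for seven
    paediatric pulmonary diagnosis groups (cystic fibrosis, asthma, primary
    ciliary dyskinesia, pneumonia, acute bronchitis, protracted bacterial
    bronchitis, and healthy controls). Patients are described by 45 ordinal
    questionnaire answers on a six-level agreement scale. An ensemble of
    eight classifiers (support vector machine, artificial neural network,
    fuzzy rule-based, random forest, multinomial logistic regression,
    regularised linear discriminant analysis, categorical naive Bayes and
    distance-weighted nearest neighbour) is fused by per-class probability
    summation into a diagnostic score with a configurable confidence limit.
    Includes stratified k-fold cross-validation with per-class sensitivity
    and one-vs-rest ROC/AUC, pairwise answer-frequency-difference heat maps,
    information-gain question ranking, and a synthetic cohort generator with
    controllable class separation for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    randomForest,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
biocViews: Classification, Software, SupportVectorMachine
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
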