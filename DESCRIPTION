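Package: erpauth
Title: ERP-Based Identity Authentication from Oddball EEG Epochs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested implementation of an event-related-potential (ERP)
    identity-authentication pipeline for 14-channel consumer EEG. Provides a
    synthetic oddball-paradigm session generator (target stimuli carry a
    positive ERP deflection, impostors do not), peak-to-peak epoch rejection,
    ensemble-average denoising, fixed-point ICA artifact separation,
    point-biserial channel and time-interval selection, statistical feature
    extraction with correlation-based best-first subset search, from-equations
    Gaussian naive Bayes, logistic-regression and back-propagation
    neural-network classifiers combined by a bagging majority-vote ensemble,
    confusion/ROC/AUC evaluation with stratified cross-validation, and a
    registration/login/authentication layer with a legal/illegal login
    benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
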