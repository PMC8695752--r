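Package: actisurv
Title: Actigraphy-Based Survival Outcome Prediction for Palliative Inpatients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, modelling and clinical evaluation of
    wrist-actigraphy time series for predicting the binary survival outcome
    (in-hospital death versus discharge in stable condition) of end-stage
    cancer inpatients. Provides a seeded synthetic-cohort generator with
    circadian rest-activity structure and frailty-coupled Karnofsky
    Performance Status (KPS) and Palliative Prognostic Index (PPI) scores; a
    preprocessing chain (horizon truncation, eligibility screening, block
    averaging, zero padding, stratified splitting); a long short-term memory
    (LSTM) sequence classifier trained with Adam on mean-absolute-error loss;
    cutoff-based KPS/PPI comparator classifiers; and diagnostic evaluation
    (confusion matrices, sensitivity/specificity/PPV/NPV/accuracy with exact
    binomial confidence intervals, ROC curves, AUC, Youden-optimal cutoffs).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
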