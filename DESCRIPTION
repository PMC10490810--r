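Package: ecgbeat
Title: ECG Beat Detection, Classification and Model Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for single-lead electrocardiogram analysis: synthetic
    annotated ECG generation, CSV and WFDB record input/output, wavelet
    soft-threshold denoising with quantitative basis selection, dual-slope
    QRS detection with adaptive two-threshold peak acceptance, fixed-length
    heartbeat segmentation under MIT-BIH and AAMI labelling schemes,
    morphological and wavelet-coefficient feature engineering, five beat
    classifiers (logistic regression, support vector machine, gradient
    boosted trees, a 1-D convolutional network and an LSTM), and ensemble
    fusion by voting and five-fold stacking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    e1071,
    nnet,
    MASS,
    xgboost,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
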