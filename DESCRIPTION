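Package: osadetect
Title: Obstructive Sleep Apnea Detection from Single-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for detecting obstructive sleep apnea (OSA) from
    single-lead electrocardiogram recordings. Provides readers and writers
    for PhysioNet-style WFDB records, QRS annotation tracks and minute-wise
    apnea label tracks (plus plain-text dialects); a signal-conditioning
    chain (zero-phase Butterworth bandpass filtering, smoothing, robust
    outlier flagging, fixed-window segmentation and per-segment
    normalization); a QRS-count window annotator; leakage-safe signal
    augmentation and a from-scratch SMOTE balancer; single-branch and
    dual-branch one-dimensional convolutional network classifiers trained
    with Adam, class weighting, early stopping, learning-rate reduction and
    checkpointing, together with decision-tree and random-forest baselines;
    gradient-based saliency maps; a full evaluation layer (confusion
    matrices, precision/recall/F1, ROC/AUC, stratified record-level k-fold
    summaries); and a deterministic synthetic ECG simulator with ground
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    rpart,
    randomForest
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
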