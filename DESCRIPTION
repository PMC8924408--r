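Package: pulmoseq
Title: Longitudinal Pulmonary Nodule Malignancy Prediction with Multiscale
    3D CNNs and a Time-Modulated LSTM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the malignancy of pulmonary nodules from
    longitudinal CT follow-up with irregular visit intervals. Provides CT
    slab preprocessing (z-axis linear resampling, nodule-centered multiscale
    3D patch extraction, intensity windowing), a two-branch multiscale 3D
    convolutional feature extractor with late fusion and a focal-style loss
    for class imbalance, a time-modulated LSTM (T-LSTM) whose gates receive
    the elapsed time between visits, a synthetic longitudinal nodule cohort
    simulator, and a train/evaluate pipeline with ROC-based metrics and
    bootstrap confidence intervals. All neural-network forward and backward
    passes are implemented in the package (Rcpp/BLAS) and guarded by
    finite-difference gradient checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    RNifti
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
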