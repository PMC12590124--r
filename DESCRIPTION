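Package: visoscil
Title: Analysis of Visually Evoked and Induced Cortical Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for the analysis of visually evoked and
    induced cortical oscillations in single virtual-sensor (source-level)
    MEG/EEG recordings. Covers trial-level preprocessing (Butterworth
    band-pass and notch filtering, epoching, stimulus-artifact
    interpolation, outlier-run exclusion), detection of visual evoked
    field/potential components from envelope-based peak picking, Morlet
    wavelet time-frequency decomposition with separate evoked and induced
    modes, 1/f spectral flattening and relative-power-change baseline
    correction, band-limited feature extraction (peak frequency, latency,
    amplitude, average power in beta, narrowband gamma and broadband
    gamma), group statistics including a cluster-based permutation test
    on time-frequency maps, and RBF-SVM classification with stratified
    resampling, ROC/AUC analysis, bootstrap AUC comparison and
    likelihood-ratio tests. A synthetic two-group cohort generator with
    known ground truth makes every stage testable without access to
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
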