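Package: slecg
Title: Single-Lead ECG Atrial Fibrillation Screening with Wavelet
    Denoising, Cross-Device Harmonization and a Compact 2-D CNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for screening atrial fibrillation in
    single-lead ECG recordings from wearable devices using a model trained
    on clinical 12-lead data. Provides periodized discrete-wavelet
    denoising with the Donoho-Johnstone universal threshold, cross-device
    signal harmonization (Fourier resampling, amplitude normalization,
    polarity detection and correction), R-peak-anchored fixed-length
    segmentation, rasterization of segments into 96x96 grayscale images, a
    compact four-block 2-D convolutional neural network with
    segment-confidence voting, decision-boundary selection, ROC/AUC
    evaluation, and a fully parameterized synthetic ECG generator that
    emulates cross-device discrepancies so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1), methods
Imports:
    stats,
    utils,
    signal,
    png,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
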