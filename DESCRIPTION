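Package: ppgarr
Title: Bradycardia and Tachycardia Detection from the Photoplethysmogram
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of photoplethysmogram (PPG) signals from RR-interval
    series with embedded bradycardia or ventricular tachycardia episodes, and
    two segment-wise arrhythmia detectors operating on 5-s windows: a
    dual-branch convolutional neural network trained on scalograms of the
    continuous wavelet transform (generalized Morse wavelets), and a
    pulse-based reference detector using template-correlation signal quality
    and rate/duration rules. Includes spectral signal-quality assessment,
    segment labeling, sensitivity/specificity with exact confidence
    intervals, Cohen's kappa detector agreement, ROC sweeps, and a
    signal-to-noise-ratio robustness study. The CNN engine (convolution,
    average pooling, dropout, Adam, early stopping) is implemented in
    C++ via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
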