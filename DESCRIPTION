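Package: ridgesnr
Title: Adaptive Wavelet-Ridge Signal-to-Noise Estimation for Wearable Biosignals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-quality assessment for wearable bioimpedance and
    photoplethysmography (PPG) heart-rate recordings. Implements an adaptive
    signal-to-noise-ratio (SNR) indicator based on continuous wavelet
    transform ridge extraction and duration-weighted ridge energy, with
    median-filter noise estimation and data-driven window selection. Also
    provides two reference estimators for comparison: an
    autocorrelation-based SNR and classical discrete-wavelet-transform
    denoising with an automatically selected threshold multiplier, plus a
    battery of normality and stationarity tests, an elliptic band-pass
    preprocessing stage, a seeded synthetic-signal generator with known
    ground truth, and batch reporting with confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    nortest,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
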