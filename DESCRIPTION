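Package: pulsecast
Title: Waveform-to-Waveform Prediction of Physiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end translation of one pulsatile physiological waveform into
    another (e.g. arterial blood pressure to intracranial pressure, or
    photoplethysmogram to blood pressure). Implements a three-step denoising
    chain (spline despiking, morphological baseline removal, zero-phase
    Butterworth bandpass), cardiac-cycle segmentation and a point-aligned
    seven-channel composite feature matrix (raw signal, per-cycle amplitude,
    pulse width, rise and fall times, first and second derivatives), the CBAnet
    sequence-regression network (local 1-D convolutions, stacked bidirectional
    LSTM, multi-head self-attention, pointwise linear readout) trained with
    AdamW under a mean-squared-error or composite shape/spectral loss,
    sliding-window inference with Hann-weighted overlap fusion, and an
    evaluation suite (RMSE, MAE, R-squared, preprocessing-improvement deltas,
    Bland-Altman limits of agreement). A seeded simulator of paired pulsatile
    signals with a known source-to-target transfer makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
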