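Package: emgagg
Title: Dataset Aggregation for Regression-Based Myoelectric Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how aggregating calibration sessions recorded on
    different days affects regression-based neuroprosthetic decoders under
    electromyographic (EMG) signal nonstationarity. Implements the full offline
    pipeline: mean-absolute-value feature extraction from multi-channel EMG
    (band-pass and notch filtering, all-pairs differential channels, 300 ms
    sliding windows at 30 Hz), reaction-lag alignment by cross-correlation,
    stepwise Gram-Schmidt forward channel selection, a least-squares-trained
    Kalman filter decoder with dead-zone thresholding, a convolutional
    regression network mapping 10-frame feature windows to 12 degree-of-freedom
    kinematics, decoding accuracy and robustness metrics (intended and
    unintended root-mean-square error, time-in-target, hold time, log mean
    absolute jerk, error-versus-days slopes), and experiment drivers for
    aggregated-training comparisons. A synthetic multi-session generator with a
    day-indexed drift process provides data with the statistical structure the
    analysis assumes, so every stage can be exercised end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
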