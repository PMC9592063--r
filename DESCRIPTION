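Package: emg2prosody
Title: Predicting Voice Pitch and Intensity Contours from Facial and Neck
    Surface Electromyography
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end research pipeline for estimating continuous voice
    fundamental-frequency (f0) and intensity contours from multi-channel
    surface electromyography (sEMG) of the face and neck, the signal setting
    of silent-speech interfaces. Provides a synthetic session generator with
    known prosodic ground truth, autocorrelation-based pitch tracking with a
    dynamic-programming path finder, Praat-style intensity contours with
    sound-pressure-level calibration, exact memory-efficient dynamic time
    warping for sEMG-to-audio alignment, a battery of twenty time-, frequency-
    and cepstral-domain sEMG feature families, stratified splitting with
    Gaussian augmentation and PCA, feed-forward deep regression networks
    trained with Adam, concordance-based evaluation metrics, and a staged
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
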