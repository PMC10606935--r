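Package: gaitropy
Title: Tsallis-Entropy Features from Detrended Insole Force-Sensor Gait Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for screening vestibular-system balance
    disorders from short insole force-sensor walks. Provides a seeded
    synthetic-cohort generator for eight-channel plantar pressure
    recordings, stance/swing segmentation with shape-preserving cubic
    Hermite upsampling, an adaptive stepwise trend-curve algorithm (plus
    polynomial baselines) that isolates fluctuation around a subject's
    habitual pressure waveform, nonadditive (Tsallis) entropy feature
    extraction from histograms of the detrended residuals, and a
    cross-validated classifier suite with confusion-matrix, ROC and
    Matthews-correlation reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    e1071,
    MASS,
    nnet,
    rpart,
    randomForest,
    kernlab,
    tibble
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
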