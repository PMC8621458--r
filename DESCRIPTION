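Package: neurofas
Title: Short-Calibration Mental Fatigue Assessment from EEG and Wristband Biosignals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate self-reported mental fatigue (Fatigue Assessment
    Scale totals) from a single five-minute multimodal recording: eight-channel
    EEG during an eyes-closed / eyes-open baseline and a four-minute auditory
    oddball task, plus wrist-worn photoplethysmography, electrodermal activity,
    skin temperature, heart rate and inter-beat intervals. Implements the full
    pipeline: zero-phase filtering and artifact subspace reconstruction, P300
    amplitude and latency detection from stimulus-locked averages, 1-s FFT band
    powers with eyes-open normalization and the complete band-ratio set,
    PPG-derived autonomic spectral indices (LF/HF, LFNU), correlation-ranked
    feature selection with reciprocal-ratio redundancy pruning, multiple linear
    regression via the normal equation, and subject-level cross-validated
    evaluation of prediction error and three-class fatigue accuracy across data
    splits, feature counts and task durations. A synthetic-cohort generator with
    plantable feature-fatigue effects makes every stage testable without any
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
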