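Package: earseiz
Title: Behind-the-Ear EEG Seizure Detection Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating seizure detection from a four-electrode
    behind-the-ear EEG montage against conventional 10-20 scalp EEG. Implements
    bipolar montage derivation, EDF and annotation input/output, a seeded synthetic
    EEG generator (1/f background, blink EOG, lateralized ictal rhythms, EMG bursts,
    electrode faults), canonical-correlation blind-source-separation muscle-artifact
    removal, blink EOG quantification via independent component analysis,
    magnitude-squared coherence channel matchup, overlapping band-power feature
    extraction, and patient-specific RBF-SVM seizure detection scored by
    leave-one-seizure-out sensitivity and false-detection rate.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    signal,
    e1071,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    broom
Config/testthat/edition: 3
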