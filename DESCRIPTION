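Package: fastcue
Title: Fast Cue-Based Training Data for Asynchronous Movement Decoding from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and offline analysis pipeline for movement-onset
    detection from the electroencephalogram (EEG). Implements a
    continuously-rotating visual cue paradigm with variable inter-trial
    intervals for rapid collection of cued movement trials, a synthetic-data
    generator producing multichannel EEG with movement-related cortical
    potentials, band-limited oscillations with event-related
    (de)synchronization, ocular artifacts and a finger-motion trace,
    preprocessing (zero-phase Butterworth filtering, regression-based
    eye-artifact removal, low-frequency feature extraction, common average
    reference), speed-threshold movement-onset detection, a shrinkage linear
    discriminant analysis (sLDA) detector with runwise cross-validated window
    length and detection delay, event-by-event evaluation (true positive rate,
    false positives per minute, refractory period, FP/min-calibrated
    thresholding), and neural-correlate analyses (movement-related cortical
    potential comparison, normalized error versus performance correlation,
    event-related desynchronization maps with bootstrap significance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
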