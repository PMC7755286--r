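Package: freesacc
Title: Single-Trial Decoding of Free Versus Instructed Saccades from
    Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for delayed oculomotor
    decision tasks recorded with stereotactic intracranial EEG. Provides a
    seeded generator of synthetic local field potentials with
    condition-specific high-gamma band-envelope effects on a 1/f
    background, EOG saccade-onset detection and behavioral statistics,
    band-envelope power feature extraction (zero-phase FIR filtering,
    Hilbert envelope, sliding-window power, baseline normalization),
    time-resolved and cross-temporal linear discriminant decoding with
    permutation maximum-statistics and binomial significance thresholds,
    exhaustive frequency-band selection, temporal-dynamics metrics
    (peaks, decoding onsets and durations, per-trial high-gamma onsets),
    and conjunction mapping of condition-specific sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
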