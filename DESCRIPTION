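Package: lfpevents
Title: Detection and Analysis of Transient 20-40 Hz Events in Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterizing transient 20-40 Hz
    oscillatory events in prefrontal local field potential (LFP) recordings
    and relating them to single-unit firing and social-interaction behavior.
    Provides zero-phase band-pass filtering, z-scored RMS envelope
    computation, envelope-threshold event detection with a minimum-duration
    criterion, Morlet wavelet spectrograms, peri-event spike rasters and
    histograms, per-cell firing-rate modulation tests, social-interaction
    zone occupancy and susceptible/resilient classification, Mann-Whitney U
    and paired t statistics with exact small-sample modes, a synthetic
    ground-truth data generator for validating every stage, plain-text file
    formats, and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
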