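Package: tonotopr
Title: Tonotopic Organization Analysis for Two-Photon and Wide-Field
    Calcium Imaging of Auditory Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis chain for mapping tonotopy in mouse primary
    auditory cortex from calcium imaging: wide-field movie preprocessing and
    low/high-frequency area localization, rigid motion correction and ROI
    trace extraction for two-photon movies, calcium transient detection with
    iterative peeling, frequency-response-area (FRA) construction and tuning
    metrics (best frequency, V/I/O shape, bandwidths, Q, monotonicity index),
    and spatial topography statistics (tonotopic gradient fits, field and
    local interquartile range of best frequency, nearest-neighbour frequency
    differences).  Ships a synthetic-data generator that emulates
    thalamocortical-recipient-like (tonotopic, narrowly tuned) and
    corticothalamic-like (non-tonotopic, broadly tuned) neuron populations,
    fluorescence traces, and movies so every stage is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
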