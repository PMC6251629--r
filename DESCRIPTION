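Package: lfpkit
Title: Hippocampal-Prefrontal Local Field Potential Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing hippocampal and
    prefrontal local field potential (LFP) recordings from freely behaving
    rodents: behavioral state segmentation from position tracking,
    per-state z-scoring, zero-phase band-pass and notch filtering,
    multitaper spectral power, theta-gamma phase-amplitude coupling
    (entropy-based modulation index), inter-areal coherence and phase-lag
    analysis with circular v-tests, and sharp-wave ripple detection.
    Includes a ground-truthed two-channel synthetic session generator so
    every stage of the pipeline can be validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
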