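Package: sleeposc
Title: Slow-Oscillation, Spindle and Ripple Analysis for LFP Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing sleep-related cortical oscillations in
    local field potential (LFP) recordings: Up/Down-state segmentation from
    the Hilbert phase of the slow oscillation, normalized-cycle Morlet
    wavelet band power with latency-to-peak extraction, sleep-spindle and
    sharp-wave-ripple detection by band-limited envelope thresholding,
    state-resolved spike-train metrics and spike-field magnitude-squared
    coherence. Includes a synthetic LFP generator with ground-truth state,
    event and spike annotations so every stage of the pipeline can be
    validated by parameter recovery, and a pipeline orchestrator that emits
    tidy per-channel metric tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
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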