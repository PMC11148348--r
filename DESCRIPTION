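Package: spikechannel
Title: Spike Propagation and Calcium Response Analysis for Engineered
    Neuronal Networks on Microelectrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for unidirectional two-node neuronal networks
    grown in axon guidance microchannels on microelectrode arrays (MEAs).
    Detects spikes from raw extracellular voltage traces using a high-pass
    Butterworth filter and a robust MAD-based noise threshold, groups
    per-electrode spikes into propagation events to quantify directionality,
    conduction speed and conduction fidelity along the channel, computes
    cohort-level morphological and functional network-integrity metrics,
    derives stimulus-evoked GCaMP dF/F0 response metrics (peak evoked
    response, sustain slope, transmission fidelity, sustained/transient
    classification), and performs concentric-shell (Sholl) neurite
    intersection analysis. Includes seed-deterministic synthetic-data
    generators for recordings, calcium traces, neurite masks and network
    cohorts so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
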