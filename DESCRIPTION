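Package: wavescan
Title: Detection and Characterization of Propagating Slow Waves on Recording Grids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A modular five-stage analysis pipeline for propagating cortical
    slow waves recorded on rectangular grids of electrodes (ECoG) or imaging
    pixels (wide-field calcium imaging). Provides signal conditioning
    (detrending, zero-phase band-pass filtering, z-scoring, background
    subtraction, spatial downsampling, logMUA estimation via Welch spectral
    ratios), three interchangeable up-state transition detectors (amplitude
    threshold with bimodal fitting, Hilbert-phase crossing, local-minima
    refinement), density-based space-time clustering of transition triggers
    into wavefronts, Horn-Schunck optical flow on the phase signal, and
    wave-wise and channel-wise characterization (velocity from delay-map
    gradients, direction, planarity, interwave intervals, wave modes, effect
    sizes). A synthetic-data generator with exact ground truth makes every
    stage testable, and a configurable orchestrator with hierarchical config
    profiles runs whole analyses end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
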