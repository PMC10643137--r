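Package: nucdyn
Title: Single-Molecule Chromatin Dynamics and Enhancer-Promoter Link Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing live-cell single-particle tracking of
    chromatin-associated protein complexes and their genomic consequences.
    Links 3D localizations into trajectories, computes four sliding-window
    biophysical parameters (anomalous exponent, apparent diffusion
    coefficient, localization length and drift magnitude), segments
    trajectories into confined and unconfined states with a Gaussian
    mixture model, resolves slow/fast chromatin-bound substates, extracts
    dwell-time kinetics with photobleaching-corrected time-lapse residence
    models, and validates every estimator against exact stochastic
    simulators (Brownian, fractional Brownian, confined Ornstein-Uhlenbeck,
    directed and state-switching motion). A second component scores
    enhancer-promoter links with an activity-by-contact model driven by
    H3K27ac activity and Hi-C contacts, calls strong links, and tests
    differential link enrichment between conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
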