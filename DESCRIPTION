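Package: ec3btsp
Title: Entorhinal Drive, Plateau Thresholds and Place-Cell Analysis for
    Hippocampal Learning Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models and analysis tools for studying how entorhinal cortex
    layer-3 (EC3) activity shapes hippocampal CA1 place-cell maps through
    behavioural-timescale synaptic plasticity. Provides a two-state
    Markov-chain simulator of EC3 persistent activity with
    environment-specific spatial tuning, a dendritic plateau-threshold
    model predicting place-field density from summed input drive, a
    complete calcium-imaging place-cell pipeline (dF/F conversion,
    significant-transient detection, noise-correlation axon merging,
    reward-aligned spatial activity maps, spatial-information shuffle
    tests, induction-lap detection, plasticity-signature metrics), and a
    seeded synthetic-data generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
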