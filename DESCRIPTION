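Package: piriform
Title: Single-Neuron Odour-Coding Analysis for Human Piriform Cortex and
    Medial Temporal Lobe Recordings
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-neuron recordings acquired during
    odour rating and identification tasks. Detects stimulus-modulated
    neurons with baseline-normalized firing rates and one-way ANOVA,
    decodes stimulus identity from pseudopopulations with a
    maximum-correlation-coefficient template classifier and
    label-permutation significance testing, and quantifies population
    sparseness, repetition suppression, valence modulation and cross-modal
    (odour/image) coding. Includes a seeded inhomogeneous-Poisson session
    simulator with full ground truth, so every stage of the pipeline can be
    exercised and calibrated without access to patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Electrophysiology, Classification, SingleCell, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
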