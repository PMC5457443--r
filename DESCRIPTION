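Package: screenomics
Title: Hit Calling for RNAi Reporter Screens and Spectral-Count AP-MS
    Interaction Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A dual-omics discovery pipeline for transcription-factor
    pathway regulators, built around an IRF5 reporter system. One arm
    analyses high-throughput siRNA reporter screens in 384-well format:
    Z-prime plate quality control, viability-gated Lucia/CellTiter-Glo
    normalization, per-plate z-scoring, replicate-concordant primary
    SMARTpool hit calling and duplex-deconvolution confirmation. The other
    arm scores affinity-purification mass-spectrometry bait-prey
    interactions from spectral counts: fold change against pooled
    negative-control purifications with background smoothing, a
    two-component Poisson posterior probability averaged over biological
    replicates (AvgP), and condition-enhancement classification. Hit lists
    from both arms are integrated into set overlaps and exportable
    interaction networks. A seeded synthetic-data generator with known
    ground truth makes every stage testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'plate-io.R'
    'simulate.R'
    'plate-qc.R'
    'hit-calling.R'
    'apms.R'
    'integration.R'
    'pipeline.R'
    'screenomics-package.R'
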