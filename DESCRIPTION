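Package: nichekit
Title: Marker Gating, Neighborhood Enrichment and Spatial Proximity
    Analysis for Imaging-Based Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing cellular niches in imaging-based spatial
    transcriptomics (CosMx SMI-style flat-file exports). Provides a
    SingleCellExperiment-derived container for multi-FOV per-cell
    coordinates and raw transcript counts, cell-level quality-control
    filters for droplet scRNA-seq and in situ panels, boolean marker-based
    cell gating, per-FOV k-nearest-neighbour neighborhood-enrichment
    matrices with receiver-abundance normalisation, nearest-target
    proximity stratification with rank-sum comparisons, per-cell-type
    expression summaries, and a deterministic synthetic-data generator
    with planted co-localisation niches for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'utils.R'
    'AllClasses.R'
    'io.R'
    'qc.R'
    'gating.R'
    'neighborhood.R'
    'proximity.R'
    'expression.R'
    'synthetic.R'
    'pipeline.R'
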