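Package: nestkin
Title: Germ-Cell Nest Detection, Flow-Cytometry Kinetics and Single-Cell
    Annotation for Spermatogonial Stem-Cell Pool Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for mapping the establishment of the
    spermatogonial stem-cell (SSC) pool in the developing mouse testis.
    Detects fluorescent germ-cell objects in 3D confocal volumes, calls
    germ-cell nests by single-linkage clustering at a physical distance
    cutoff, and summarises nest statistics; gates flow-cytometry event
    tables (lineage-label background gating, reporter-intensity tertiles,
    DNA-content cell-cycle fractions) into developmental-kinetics tables;
    and applies single-cell RNA-seq quality filtering, germ-cell selection,
    variable-gene selection, graph clustering with an enrichment-based
    resolution criterion, marker dot-plot statistics and replicate matrix
    correlation. Seeded synthetic-data generators provide ground-truthed
    image volumes, cytometry tables and count matrices for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    igraph,
    EBImage,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
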