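Package: clonotrace
Title: Clone-Informed Analysis of Single-Cell Lineage-Tracing Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates single-cell transcriptomic embeddings with clonal
    labels (lineage barcodes or TCR clonotypes) to estimate smoothed clone
    density profiles by label propagation on a cell kNN graph, compare
    clones by earth mover's distance over graph-geodesic costs, embed and
    cluster clones into clonotype profiles, infer clone-informed pseudotime,
    quantify clone plasticity, and detect fate-driving genes with a
    soft-assignment nested F-test. Includes a branching-trajectory simulator
    with ground truth for benchmarking, and a baseline differential
    expression comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    RANN,
    splines,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    rhdf5,
    uwot
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
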