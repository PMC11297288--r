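Package: cpbench
Title: Benchmarking Batch-Correction Methods for Image-Based Morphological Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale benchmark framework for batch-effect correction of
    well-level image-based (Cell Painting style) morphological profiles.
    Provides a validated profile container with plate/batch/source metadata,
    the four-step preprocessing pipeline used for such profiles (low-variance
    filtering by robust coefficient of variation, plate-wise median absolute
    deviation normalization on negative controls, rank-based inverse normal
    transformation, and correlation-threshold feature selection), reference
    implementations of batch-correction methods with a uniform fit/apply
    contract (sphering/ZCA whitening on controls, ComBat, mutual
    nearest-neighbour correction, a Harmony-style iterative cluster
    correction), ten integration metrics (batch/label silhouette, graph
    connectivity, iLISI/cLISI, kBET, Leiden ARI/NMI, and replicate-retrieval
    mean average precision), a hierarchical synthetic-profile simulator with
    ground-truth oracle correction, and scenario orchestration with weighted
    score aggregation and UMAP diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    cluster,
    FNN,
    igraph,
    jsonlite,
    matrixStats,
    stats,
    sva,
    utils,
    uwot,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
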