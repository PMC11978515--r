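Package: srtqc
Title: Quality Assessment and Benchmarking Toolkit for Imaging-Based
    Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality-control, specificity and benchmarking metrics for
    imaging-based spatially resolved transcriptomics (SRT) data such as
    10x Genomics Xenium. Implements per-read quality filtering, negative
    marker purity (NMP) with permutation rescaling, negative co-expression
    purity (NCP), gene detection-efficiency ratios against an annotated
    scRNA-seq reference, an optimal nuclear-expansion estimator based on
    distance-binned expression signatures, segmentation-output evaluation
    (mask expansion, read assignment, majority-vote cell typing, a
    background-intensity false-cell filter), a preprocessing-workflow
    benchmark with cluster-count-matched resolution tuning and
    partition-similarity metrics, imputation metrics with k-fold gene
    cross-validation, control-probe false-positive quantification, a
    kernel-density z-axis coherence score, and a seeded simulator that
    turns annotated single-cell references into Xenium-like datasets and
    spatial point-cloud fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    methods,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    arrow,
    mclust,
    optparse,
    tiff,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
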