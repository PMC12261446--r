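Package: spotbench
Title: Simulation and Evaluation Toolkit for Benchmarking Spot
    Deconvolution on Spatial Multiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates benchmark datasets for spot-level deconvolution of
    spatial chromatin accessibility and transcriptomics data, and evaluates
    deconvolution results against known cell-type composition.
    Silver-standard spots are simulated from a dissociated single-cell
    multiome reference by sampling per-spot cell density and cell-type
    heterogeneity from a Poisson-Gamma (negative binomial) distribution,
    optionally with spatially zonated composition (stripes or circles).
    Gold-standard pseudo-spots are built by binning spatially tagged single
    cells on a regular grid and summing their profiles. The package also
    provides the accompanying feature-selection strategies (highly
    accessible peaks, highly variable peaks across cell-type clusters,
    dispersion-based highly variable genes), an evaluation metric stack
    (RMSE, Jensen-Shannon divergence, normalized mutual information,
    rare-cell-type F1, paired Wilcoxon strategy comparison), a naive
    majority baseline, and a non-negative least-squares reference
    deconvolver, plus Matrix Market/TSV readers and writers so external
    deconvolution tools can be benchmarked through a simple proportions
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    BiocGenerics,
    IRanges,
    Matrix,
    methods,
    pracma,
    S4Vectors,
    SingleCellExperiment,
    stats,
    SummarizedExperiment,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
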