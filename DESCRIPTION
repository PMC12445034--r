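Package: svgbench
Title: Benchmarking Toolkit for Spatially Variable Gene Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators, a baseline detector, and evaluation metrics for
    benchmarking spatially variable gene (SVG) detection methods on spatial
    transcriptomics and spatial ATAC-seq data. Provides a reference-based
    simulator that fits per-gene negative binomial models with Gaussian-process
    smoothed spatial means and synthesizes counts with a controlled fraction of
    spatial variability, a multi-kernel Gaussian-process simulator for
    scalability studies, a Moran's I detector with permutation and analytic
    p-values, and the evaluation suite (Kendall's tau, area under the
    precision-recall curve, Kolmogorov-Smirnov calibration distance, adjusted
    Rand index, CHAOS spatial continuity, cross-dataset rank aggregation) so
    that any SVG detector producing a per-gene score table can be scored
    against known ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    mgcv,
    RANN,
    rhdf5,
    igraph,
    irlba,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
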