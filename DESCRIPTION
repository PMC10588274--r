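Package: scvarkit
Title: Cell-to-Cell Expression Variability Metrics and Benchmarking for
    Single-Cell Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for quantifying and benchmarking per-gene
    cell-to-cell expression variability in single-cell RNA-seq count
    matrices. Implements a panel of variability metrics spanning generic
    statistics (SD, MAD, IQR, CV, Fano factor), a windowed local
    coefficient of variation, distance-to-median with gene-length
    correction, mean-variance trend decomposition, binned dispersion
    z-scores, LOESS-standardized variance, and a shrunken
    negative-binomial dispersion estimator. Includes a multi-criterion
    evaluation framework (Kolmogorov-Smirnov platform and cell-type
    distances, data-structure association scores, gene-set and
    highly-variable-gene rediscovery, subsampling stability, and
    negative-control dispersion), a gamma-Poisson count simulator with
    ground-truth highly variable genes and logistic dropout, a
    differential-variability test between conditions, a lineage trend
    classifier, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
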