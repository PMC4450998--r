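Package: scdiverge
Title: Cell-to-Cell Expression Divergence Analysis for Single-Cell RNA-Seq Tag Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and testing cell-to-cell variability in
    single-cell RNA-seq tag-count data. Implements spike-in-based library
    quality control (leave-one-out 2-SD rule), rpkm quantification, the
    per-gene relative divergence statistic (coefficient of variation of rpkm
    across cells), classification of more- and less-diverse genes against
    expression-matched control genes by a variance-ratio F-test, Fisher's
    exact gene-set enrichment, comparison of conditions by fold changes of
    means and relative divergences, saturation analyses under binomial
    depth thinning and cell subsampling, hierarchical clustering and PCA of
    cells, and a negative-binomial synthetic-data generator with a truth
    table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    Matrix,
    yaml,
    withr,
    stats,
    utils,
    methods,
    GenomicRanges,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
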