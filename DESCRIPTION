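Package: bivarseg
Title: Bivariate Structural-Change Segmentation of SNP-Array Tumour Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint segmentation of the log R ratio (LRR) and informative
    mirrored B allele frequency (imBAF) signals from SNP arrays of tumour
    samples. Segment boundaries are found by exact dynamic programming over a
    piecewise-constant bivariate model whose per-segment energy combines the
    residual sums of squares of the two variables through a Minkowski distance
    of configurable order, weighted by the number of observed values in each
    variable. The number of segments is chosen by a BIC-penalised Gaussian
    log-likelihood. The package ships a synthetic tumour-sample generator
    (copy-number and loss-of-heterozygosity alterations under normal-cell
    contamination) and a windowed change-point scoring protocol, so the whole
    method can be exercised and benchmarked without any real array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
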