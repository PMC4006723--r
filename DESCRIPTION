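Package: oriscan
Title: Resolution-Controlled Detection of DNA Replication Origins from
    SNS-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects DNA replication origins from short-nascent-strand (SNS)
    sequencing read-start profiles with a fixed-resolution sliding-window scan
    whose significance threshold is derived from a compound-Poisson
    (Poisson-geometric) null model and adapts to regional coverage through
    Poisson changepoint segmentation.  Includes the downstream comparative
    toolkit: origin clustering and overlap with randomization-based expected
    overlap, constitutive/common/specific classification across cell lines,
    mean replication timing from six-fraction Repli-Seq signal with six timing
    categories, G-quadruplex motif scanning, randomization-based feature
    enrichment, stratified efficiency/length/density summaries, and linear
    discriminant analysis of origin-to-chromatin-mark distances.  A seeded
    synthetic-data generator reproduces the statistical structure the
    detection model assumes, so the whole toolkit is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
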