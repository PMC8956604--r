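Package: crisprhit
Title: Hit Calling and Tumor-Immune Association for CRISPR Activation Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of pooled CRISPR activation screens for
    resistance to T cell cytotoxicity: guide-count normalization, log fold
    change, robust rank aggregation with a permutation null, empirical false
    discovery rates against housekeeping negative-control genes, replicate
    overlap candidate selection, hypergeometric pathway enrichment with
    redundancy pruning, cytolytic-activity correlation across tumor cohorts,
    and single-sample gene set enrichment (ssGSEA) comparison of
    immunotherapy responders and nonresponders. Includes negative-binomial
    screen and expression-cohort simulators with planted, recoverable signal
    for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    fgsea,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
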