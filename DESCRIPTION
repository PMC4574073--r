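Package: repeatcohort
Title: Tandem Repeat Instability in Paired Tumor-Normal Genome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects tandem repeats in gene promoters and exon
    super-transcripts of paired genomes, calls per-gene repeat instability
    (de-novo gain/loss "orphans" and copy-number variation) between tumor and
    matched normal genomes against an all-pairs normal-normal null, and tests
    association of promoter repeat instability with gene expression and
    promoter methylation. Includes a synthetic paired-cohort generator with a
    replication-slippage mutation model so the whole pipeline is testable
    without controlled-access data, a wraparound dynamic-programming repeat
    scorer, rank-based cohort statistics, and pathway-level enrichment
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
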