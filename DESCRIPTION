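Package: CNVconcord
Title: Multi-Caller Copy Number Variant Harmonization and Relatedness-Based Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for integrating copy number variant (CNV) calls made by
    multiple calling programs on the same samples. Applies marker-count and
    size inclusion filters, merges adjacent same-status call fragments by a
    gap-fraction rule, matches calls within and between individuals by
    reciprocal overlap with gain/loss state agreement, partitions merged
    events by caller membership (Venn-style), and quantifies pairwise
    call-set difference (the d statistic) across known degrees of genetic
    relatedness (monozygotic twins, parent-child, unrelated). Includes a
    relatedness-aware synthetic cohort simulator with per-caller error
    models so the whole pipeline can be exercised and validated without
    array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
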