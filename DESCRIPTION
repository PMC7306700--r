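Package: plastdom
Title: Positional Gene Clusters, Their Conservation, and H3K27me3 Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects chromosomal clusters of differentially expressed genes
    with a sliding-window hypergeometric scan (gene-based or base-pair
    windows), assesses genome-wide cluster enrichment against an
    expressed-gene background by bootstrap resampling, scores cross-species
    conservation of cluster gene order with a longest-common-subsequence
    statistic, and profiles ChIP fold enrichment (e.g. H3K27me3) across
    length-normalised clusters and their half-length flanks. Includes a
    synthetic-data generator that emulates a fragmented insect genome
    annotation, differential-expression lists with planted clusters,
    diverging ortholog tables, and condition-specific enrichment tracks,
    so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
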