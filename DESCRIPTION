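Package: peakfam
Title: Unsupervised Protein Family Discovery by Density Peak Clustering
    of Local Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies putative protein domain families from tabular local
    pairwise alignments (BLAST outfmt 6) without supervision. Alignments on
    each query sequence are grouped by interval Jaccard distance into
    "primary clusters" (domain-like regions) with Density Peak Clustering;
    primary clusters are then clustered across queries into "metaclusters"
    (putative families) according to the search-sequence regions they share,
    merged, filtered, and exported as seed sets for profile-HMM construction.
    Includes the evaluation machinery for comparing metaclusters against a
    reference domain classification (ground-truth architectures, consistency
    percentages, boundary agreement, coverage curves, normalized mutual
    information) and a synthetic proteome/alignment simulator with planted
    multi-domain architectures for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    data.table (>= 1.14.0),
    Biostrings,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
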