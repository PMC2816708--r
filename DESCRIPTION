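Package: regscan
Title: Promoter Motif Over-Representation, E-Box Positional Analysis and
    Gene-Set Enrichment for Regulatory Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking transcription-factor motifs to expression
    responses: strand-aware promoter window extraction from FASTA/BED,
    TRANSFAC and JASPAR matrix parsing, exact-consensus and position-weight
    matrix scanning against an order-0 background model with a
    posterior-odds prior threshold, binomial motif over-representation with
    a Bonferroni-style significance score, canonical E-box (CACGTG)
    positional profiling, a two-sample t-test differential-expression
    filter cascade with two-cell-line cross-comparison, observed-vs-expected
    chi-square enrichment of clustered target-gene catalogs, Fisher-exact
    pathway enrichment with bipartite pathway-gene network reconstruction,
    and seeded synthetic-data generators with planted ground truth for
    every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
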