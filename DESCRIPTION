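Package: pirnascan
Title: Discovery of Candidate piRNAs from Multi-Copy Noncoding RNA Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for tracing candidate PIWI-interacting
    RNAs (piRNAs) from spliced long noncoding RNA transcripts of a multi-copy
    genomic locus to putative target sites in untranslated regions (UTRs) of
    protein-coding genes. Provides splice-aware transcript-to-genome alignment
    with canonical GT..AG junction placement, classification of alternative
    splicing events between isoforms, mismatch-tolerant scanning for short
    (10-30 nt) homology stretches in UTR sets with exon versus exon-junction
    localization, exact multi-copy genome mapping of piRNA-sized reads with
    chromosome-exclusivity reporting, and relative copy-number estimation from
    qPCR Ct tables by the Livak 2^-ddCt method. A ground-truthed synthetic
    data generator emulates every input so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
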