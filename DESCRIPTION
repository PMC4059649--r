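Package: lincFinder
Title: Discovery and Characterization of Long Intergenic Non-Coding RNAs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for genome-wide identification and characterization
    of long intergenic non-coding RNAs (lincRNAs) from assembled RNA-Seq
    transcripts and predicted gene models. Overlapping transcripts and genes
    are merged into transcript units, which are passed through a filter
    cascade (removal of gene-overlapping units, sequence-similarity hits,
    long open reading frames, short transcripts, and units with positive
    coding potential). Surviving candidates are characterized by their
    adjacent protein-coding gene context and orientation configuration,
    strand-of-origin calls from RACE-style band patterns, and qPCR delta-Ct
    expression profiling with Pearson-correlation classification across
    developmental stages. A synthetic-data generator with a ground-truth
    manifest makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Transcriptomics, GenomeAnnotation, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
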