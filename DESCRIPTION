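Package: retromark
Title: Linking Methylated Chromatin-Associated RNAs to Retrotransposon
    Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for studying how N6-methyladenosine (m6A) marks
    on chromatin-associated RNAs relate to retrotransposon silencing.
    Implements knockout-sensitivity classification of modification peaks,
    repeat-subfamily expression quantification with differential calling,
    peak/feature relative-enrichment statistics, ChIP IP/input signal
    intensity and peak-change classification, IUPAC motif density, percent
    spliced in (PSI), metagene body profiles, and cross-condition Venn
    classification with a hypergeometric overlap test. Ships a synthetic-data
    generator that emulates the statistical structure of chromatin m6A-seq,
    repeat RNA-seq and ChIP-seq experiments so that every stage of the
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
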