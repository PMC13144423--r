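Package: polvterm
Title: Sequence-Level Analysis of RNA Polymerase V Transcription Termination Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating and quantifying the A-rich-template (T-rich
    non-template) DNA signal associated with spontaneous termination of plant
    RNA polymerase V. Implements a strand-specific windowed T-score/AT-score
    richness statistic with a consecutive-run bonus and longest-opposite-run
    penalty, homopolymer track frequency statistics at transcript 3' ends,
    poly-tract anchoring, termination-region classification of nascent
    transcripts against polymerase-bound transcript annotations, strand-aware
    metagene profiling around transcript end sites with an upstream/downstream
    Welch comparison, and a synthetic-genome generator that plants termination
    tracts and NET-seq-like 3'-end signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
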