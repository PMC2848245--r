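Package: ltrquant
Title: Quantifying LTR Retrotransposon Transcription with Multi-Mapping
    Bounds and Permutation Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring transcription of long terminal repeat (LTR)
    retrotransposons in compact genomes such as fission yeast, where near
    identical repeat copies make read and probe assignment ambiguous.
    Partitions LTR annotations into full-length elements and solitary LTRs,
    maps short reads and strand-tagged tiling probes by exact matching with
    exclusive/unique filters, brackets per-locus activity between an
    equal-split lower scenario and a single-locus upper bound, projects
    signal onto multiple alignments and flank coordinate frames, and tests
    locus-level expression variance and LTR-gene time-course coupling with
    dedicated permutation procedures. A synthetic-data generator produces
    toy genomes, probe tables and staged read sets with known ground truth
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
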