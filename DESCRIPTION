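Package: hervtrace
Title: Integration-Site Discovery for HERV-K Retrotransposition from
    Ligation-Mediated PCR Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting endogenous retrovirus (HERV-K)
    retrotransposition from ligation-mediated PCR (LM-PCR) junction
    sequencing libraries. The package simulates LM-PCR libraries with full
    ground truth (proviruses planted with integrase-style target-site
    duplications, sonication shear-length diversity, PCR duplicates,
    substitution errors), filters reads on per-position index-read quality,
    detects and trims the terminal 3' LTR hexamer to recover host junction
    segments, maps them with a deterministic unique-best ungapped k-mer
    mapper, deduplicates molecules, calls integration sites, verifies
    retrotransposition hallmarks (target-site duplication length, U3 versus
    CMV 5' junction, reporter intron removal), estimates clone copy numbers
    by distinct-amplicon counting, and classifies loci across samples into
    reference, nonreference-universal and nonreference-specific sets with
    matching against known polymorphic insertions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
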