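Package: scfvlib
Title: Design and Quality Control of Semisynthetic scFv Phage-Display Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing and quality-controlling semisynthetic
    single-chain variable fragment (scFv) phage-display antibody libraries
    built by oligonucleotide-directed (Kunkel) mutagenesis of the heavy- and
    light-chain CDR3 loops. Covers degenerate-codon algebra (IUPAC expansion,
    genetic-code translation, exact combinatorial diversity with arbitrary
    precision integers), Kabat-labelled CDR3 cassette construction with
    short/long length sublibraries, restriction-site checks for parental
    template depletion, mutagenesis-primer quality control (GC balance,
    melting temperature, equimolar pooling), sequenced-repertoire analysis
    (CDR3 extraction, length and per-position diversity, residual-template
    detection, library-size estimation), panning/ELISA screening triage,
    and a seeded synthetic-data generator with ground-truth tables so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
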