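Package: piRNApatterns
Title: Detection of Ping-Pong and Short By-Product Signatures in Small RNA Reads
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of piRNA processing signatures in mapped
    small-RNA sequencing reads. Computes the sense/antisense 5'-end distance
    spectrum with a weighted-minimum pairing rule, detects the ping-pong
    duplex pattern (5' offset 9) and the 19-nt by-product pattern (5' offset
    28), tests their co-localization by positional cross-correlation,
    enumerates triplex loci, fits a two-state Markov model of strand bias,
    and summarizes first-nucleotide composition and guide/product length
    distributions. Includes a synthetic read simulator with planted loci and
    a ground-truth table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
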