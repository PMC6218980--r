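Package: palinclean
Title: Detection and Splitting of Palindromic Chimeras in Long Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Whole-genome amplification can fold a DNA fragment back on
    itself, producing chimeric long reads in which a sequence is immediately
    followed by its own reverse complement. palinclean detects such
    artificial palindromes by aligning each read against its reverse
    complement with an exact Smith-Waterman local alignment, splits flagged
    reads at the palindrome center, and recurses on the halves so that
    nested palindromes are resolved into clean sub-reads without editing a
    single base. The package also ships a chimera simulator with ground
    truth, read-set summary statistics (palindrome incidence, length and GC
    profiles, split-iteration histograms), streaming FASTA/FASTQ support,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
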