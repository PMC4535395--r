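Package: rbsmeth
Title: RNA Bisulfite Sequencing Analysis of 5-Methylcytosine in tRNAs and rRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects 5-methylcytosine (m5C) sites in transfer and ribosomal
    RNAs from RNA bisulfite sequencing (RBS-seq) data at single-nucleotide
    resolution. Provides tRNA isodecoder consensus collapsing, in-silico
    cytosine-to-thymine reference conversion, three-letter (bisulfite-aware)
    ungapped read alignment, per-cytosine pileup and percent-methylation
    calling with spike-in conversion-efficiency quality control, mapping of
    called sites onto the representative 72-position tRNA cloverleaf and onto
    anchor-based rRNA coordinates, cross-species conservation classification,
    and in-silico methyl-chop PCR / dCAPS restriction-digest prediction.
    Includes a bisulfite read simulator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
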