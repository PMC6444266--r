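Package: plastvar
Title: Comparative Plastome Variation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of chloroplast genomes
    (plastomes): detection of the quadripartite LSC/IRb/SSC/IRa structure,
    MISA-style simple sequence repeat (SSR) scanning with region and
    genic-context stratification, SNP calling from a multiple sequence
    alignment with a six-class non-strand-specific substitution spectrum,
    indel calling with microsatellite-related (SSR-indel) versus
    non-repeat (NR-indel) classification and polarity, small-inversion
    detection with inverted-repeat flank verification, and sliding-window
    nucleotide diversity (pi) with mutational hotspot calling. Includes a
    synthetic plastome-quartet simulator that plants SSR loci and
    SNP/indel/inversion events with a machine-readable truth ledger, so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
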