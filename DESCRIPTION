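Package: phasiforge
Title: Discovery of miRNAs, isomiRs and Phased siRNAs from Plant Small RNA
    Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for annotating plant small regulatory
    RNAs from collapsed deep-sequencing libraries mapped to a reference
    sequence set. Identifies miRNA hairpin precursors using structural
    filters (minimum free energy, MFEI, AMFE, GC content, duplex
    mismatches) and read-bias filters (single-strand bias, abundance
    bias); classifies end-variant isomiRs; detects 21-nt phased
    siRNA-producing gene transcripts (PGTs) with a hypergeometric phasing
    statistic; scores sRNA-transcript target sites with a plant-target
    penalty scheme to predict phasing triggers and cis/trans cleavage
    networks; and tests tissue differential expression of read counts
    with a pooled two-proportion Z-test and Benjamini-Hochberg FDR.
    Includes a synthetic-data generator that plants hairpins, phase
    registers, triggers and tissue effects with a ground-truth manifest,
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
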