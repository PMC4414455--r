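Package: mirstress
Title: Small RNA Sequencing Analysis of Plant miRNAs Under Heavy-Metal Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for two-library plant small RNA
    sequencing studies without a reference genome: adapter trimming and
    read cleaning, collapsing to unique sequence tags, priority-rule
    annotation against non-coding RNA references, conserved miRNA
    identification by mismatch-bounded matching to known mature miRNAs,
    novel miRNA prediction from transcript hairpins using a
    nearest-neighbor folding energy model (MFE and MFEI criteria), isomiR
    cataloguing, complementarity-based miRNA target prediction with G:U
    wobble scoring, and Audic-Claverie differential expression between an
    untreated and a treated library. Includes a seeded synthetic-data
    generator that emulates two adapter-ligated libraries drawn from
    planted pre-miRNA hairpins, ncRNA fragments and background reads, so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
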