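Package: horscan
Title: Higher-Order Repeat Structure Detection in Satellite DNA Long Reads
Version: 1.0.0
Authors@R:
    person("horscan", "developers", email = "horscan@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies higher-order repeat (HOR) structure in
    satellite-DNA-containing long reads, read by read and without assembly.
    Monomers (~171 bp alpha-satellite repeat units) are located on both
    strands with a built-in semi-global aligner or ingested from an external
    profile-HMM hit table, clustered by O(ND) edit-distance identity with a
    98-88 percent threshold scan, and evaluated against four regularity
    conditions to call each read regular, irregular (with inversion
    annotation) or no-HOR (including divergent monomeric satellite).  Also
    estimates the HOR period, emits per-read consensus sequences, exports
    >= 1 kb non-satellite transition regions for external annotation, and
    includes a ground-truth synthetic read simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
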