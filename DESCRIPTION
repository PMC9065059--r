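Package: g4splice
Title: G-Quadruplex Motif Topography Around Splice Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genome-wide analysis of G-quadruplex (G4) consensus motifs and
    G-run blocks around splice sites and their association with alternative
    splicing. Provides a strand-aware consensus motif scanner, splice-site
    extraction from gene models with template/non-template strand context,
    position-weight-matrix splice-strength scoring, positional metaprofiles
    with median normalization and Wilson confidence bands, a
    dinucleotide-preserving permutation null (Altschul-Erickson shuffle),
    delta-PSI contingency statistics with Yates-corrected chi-squared and
    Bonferroni adjustment, sQTL/SNP adjusted enrichment tracks, binned
    eCLIP differential-binding profiles with Ward clustering, and seeded
    synthetic-data generators with planted ground truth so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
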