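Package: codonstab
Title: Coding-Region Determinants of Human mRNA Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for isolating coding-region effects on mRNA stability:
    half-life estimation from 4-thiouridine approach-to-equilibrium time
    courses by bounded-growth nonlinear least squares with spike-in
    normalization, ORFeome reporter transcript classification, codon and
    amino-acid stability coefficients (CSC/AASC) with frameshift controls,
    ribosome-profiling A/P/E-site codon pause scores, ORF-level sequence
    features, and a seeded synthetic-data generator with known ground truth
    for end-to-end recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
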