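Package: repeatdca
Title: Identity-Equalized Direct Coupling Analysis for Tandem-Repeat Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Direct coupling analysis (DCA) tailored to tandem-repeat protein
    families. Builds concatenated n-neighbour repeat alignments from
    repeat-unit multiple sequence alignments, computes mean-field direct
    information (DI) with Henikoff sequence weighting and a scrambled-column
    finite-size correction, and implements an identity-equalized variant
    (DI_id) that removes the spurious (i, i+L0) coupling diagonal caused by
    high sequence identity between consecutive repeats. Includes adaptive
    clustering of DI values to select co-evolutionary hits, evaluation against
    structural contact maps, reconstruction of multi-repeat coupling matrices
    from pairwise calculations with an exponential decay fit of inter-repeat
    signal, subsampling-based convergence analysis, and a Potts-model
    generator of synthetic repeat alignments with a tunable repeat-duplication
    bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Matrix,
    stats,
    utils,
    Biostrings,
    bio3d,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
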