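Package: bppnet
Title: Neural Inference of RNA Base-Pairing Probabilities with MEA
    Decoding of Pseudoknotted Secondary Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts RNA secondary structures, with and without
    pseudoknots, by inferring base-pairing probabilities directly with
    neural networks instead of a thermodynamic or grammar-based partition
    function.  Two probability models are provided: a feedforward network
    over k-mer contexts around each candidate base pair and a
    bidirectional recursive network over the derivation structure of a
    simple RNA grammar.  Structures are decoded from the probability
    matrix by maximum-expected-accuracy (gamma-centroid) criteria:
    Nussinov-style dynamic programming for pseudoknot-free structures and
    a hierarchical integer program, solved exactly by a specialized
    branch-and-bound algorithm, for pseudoknotted structures.  Models are
    trained end-to-end with a structured support vector machine
    (max-margin) objective via loss-augmented decoding and stochastic
    subgradient descent.  Includes readers and writers for FASTA, BPSEQ,
    CT, extended dot-bracket and plain-text probability matrices, a
    seeded generator of synthetic RNA families for testing, and
    sensitivity/PPV/F evaluation of predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
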