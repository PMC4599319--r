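Package: msastab
Title: Tied Distances and Input-Order Instability in Progressive Multiple
    Sequence Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study why progressive multiple sequence alignment is
    unstable under input-order changes. Implements the k-tuple pairwise
    distance formula families used by Clustal Omega, Muscle, Kalign and Mafft
    (plus a Needleman-Wunsch identity distance), a census of tied distance
    values in a matrix together with closed-form maxima for the number of
    unique distances and the number of sequences that can be aligned before
    ties must appear, UPGMA guide-tree construction with explicit tie
    detection and pluggable tie-breaking policies, a minimal
    Feng-Doolittle-style progressive aligner with deterministic traceback, a
    core-column TC score against a reference alignment, and a synthetic
    protein-family simulator with a known true alignment so that
    forward/reverse instability experiments run at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    Biostrings,
    ape,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
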