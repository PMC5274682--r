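Package: periscan
Title: Latent DNA Periodicity Detection by Weight-Matrix Optimization
    with Indel-Tolerant Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects highly diverged (latent) tandem periodicity in DNA
    sequences.  A position weight matrix over the period positions is
    optimized by a genetic algorithm whose fitness is the score of an
    indel-tolerant local alignment between the sequence and a cyclic
    profile of the period columns.  Includes shuffle-null significance
    calibration, a sliding-window genome scanning protocol with a
    triplet-periodicity filter for protein-coding-like windows, an
    information distance between period frequency matrices for
    cross-genome repeat comparison, chromosomal density profiles of
    periodicity scores, and a simulator of latent tandem arrays with
    substitutions and indels for benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
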