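Package: crossreg
Title: Cross-Species Regulatory Sequence Activity Modeling
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Train a single sequence-to-signal convolutional neural network
    jointly on two genomes with leakage-free, homology-aware holdout splits,
    and use it for allele-difference variant effect scoring and downstream
    statistical analyses (cross-species transfer evaluation, matched-negative
    classification, case/control de novo variant tests). Includes a synthetic
    two-species benchmark generator with a shared regulatory grammar so the
    full pipeline runs at desk scale on a CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    VariantAnnotation
Config/testthat/edition: 3
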