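Package: mirtarprobe
Title: Interpretation of miRNA-Target Deep Learning Classifiers by In Silico Mutagenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for asking what a hybrid convolutional/recurrent miRNA
    target-site classifier has learned. Provides a synthetic generator of
    labelled miRNA:target-site pairs with planted, ground-truth-known
    complementarity; a compact trainable surrogate network (embedding,
    convolution, max-pooling, bidirectional GRU, dense layers) exposing
    prediction probabilities and named-layer activations; an in silico
    mutagenesis engine (region occlusion, sliding k-nucleotide scans,
    Mann-Whitney U significance with Bonferroni correction); accumulative
    per-nucleotide impact profiles built by differencing adjacent mutation
    widths, with greedy feature-region selection; a wobble-aware affine-gap
    duplex aligner yielding binding-energy scores and region base-pairing
    statistics; Spearman correlation of per-unit, per-feature-map and
    whole-layer activations with binding energy; and a pipeline orchestrating
    all stages from one configuration with a run manifest and report
    rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
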