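Package: eggcandler
Title: Lightweight Anchor-Free Detection of Fertile and Infertile Eggs on
    Candled Incubation Trays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and classifying fertile versus infertile
    eggs on candled incubation trays with a lightweight anchor-free
    convolutional detector (LDA) derived from the YOLOX-Tiny family.
    Provides a symbolic computation-graph auditor that reports exact
    trainable-parameter and FLOP counts for every network variant
    (CSP block variants, backbone variants, depth-wise separable
    substitution, efficient channel attention), an executable CPU
    forward/backward engine for the same graphs, a seeded synthetic
    candled-tray image generator with PASCAL VOC annotation I/O and a
    x4 augmentation pipeline, SGD training with a cosine-annealing
    learning-rate schedule, and VOC-style precision/recall/AP/mAP
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    xml2,
    jsonlite,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
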