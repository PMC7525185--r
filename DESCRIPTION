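Package: skfcnn
Title: CircRNA-Disease Association Prediction via Similarity Kernel Fusion and a Convolutional Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts circRNA-disease associations from heterogeneous
    biological networks. Builds circRNA similarity kernels (sequence,
    miRNA-regulatory, expression, Gaussian interaction profile) and disease
    similarity kernels (DAG-based semantic, Gaussian interaction profile,
    plus precomputed kernels), fuses each side into a single kernel by
    iterative cross-diffusion with a mutual-neighbour weight mask, assembles
    a two-row feature matrix per candidate pair (fused similarities,
    association profiles, and PCA-compressed miRNA interaction profiles),
    and classifies pairs with a compact two-layer convolutional network.
    Includes negative sampling, repeated k-fold cross-validation with the
    standard panel of classification metrics, candidate ranking, and a
    planted-block synthetic study generator so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    igraph,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
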