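Package: rosettesim
Title: Synthetic Arabidopsis Rosettes for Training Leaf-Counting Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A stochastic parametric L-system model of the Arabidopsis
    thaliana rosette that renders labeled top-down images, dataset builders
    for synthetic leaf-counting datasets, and a convolutional neural network
    count regressor with its training regime, image augmentations, evaluation
    metrics and experiment drivers (augmentation, generalization under
    dataset shift, interoperability between real and synthetic data).
    Includes a minimal timed parametric L-system engine with 3D turtle
    interpretation and a deterministic software rasterizer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    png,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
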