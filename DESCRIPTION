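Package: gwascnn
Title: Color-Image Genotype Encoding and Convolutional Neural Networks
    for Case/Control GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts case/control SNP genotype matrices into images and
    classifies disease status with a small convolutional neural network,
    then screens candidate risk SNPs from gradient-weighted class
    activation maps (Grad-CAM). Implements a color genotype encoding
    (one RGB channel per genotype class) alongside two grayscale
    baseline encodings, a case/control genotype simulator with planted
    relative risks, standard GWAS quality-control filters and the
    allelic chi-square association pre-screen, Bayesian (Gaussian
    process, expected improvement) hyperparameter optimization of the
    network, and a staged command-line pipeline. The network
    (three convolution + max-pooling stages, dropout, softmax) is
    implemented in the package with Rcpp kernels; no external deep
    learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    lhs,
    png,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
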