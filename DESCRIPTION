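Package: ganterfactual
Title: Counterfactual Explanation Images for Binary Classifiers via
    Classifier-Guided CycleGAN
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates counterfactual explanation images for a binary image
    classifier by training an unpaired image-to-image translation system
    (CycleGAN: two generators and two PatchGAN discriminators) whose
    objective is extended with a counterfactual loss penalizing translated
    images the frozen classifier does not assign to the opposite class.
    Includes a synthetic lung-phantom corpus generator, an AlexNet-style
    binary classifier trained with SGD on a mean-squared-error loss,
    flip-rate confusion-matrix evaluation against a plain CycleGAN
    ablation, explanation export with linear interpolation frames, and a
    command-line interface. All networks run on a compact built-in CNN
    engine (im2col convolutions compiled via Rcpp, BLAS matrix products).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
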