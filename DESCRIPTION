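Package: fundusvit
Title: Contour-Guided and GAN-Augmented Vision Transformers for Glaucoma Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, CPU-scale implementation of a contour-guided,
    augmentation-heavy vision-transformer workflow for multi-class glaucoma
    grading from colour fundus photographs. Provides a seeded synthetic
    fundus-phantom generator (class-conditional optic disc/cup geometry) so
    the whole pipeline is testable without clinical data; a Canny-style
    contour-extraction chain (Gaussian smoothing, Sobel gradients,
    non-maximum suppression, hysteresis) with circular-Hough optic-disc
    localisation and intensity-based cup segmentation; classical per-class
    augmentation budgeting; a conditional GAN with an encoder-generator
    reconstruction path, auxiliary classifier loss and WGAN-GP gradient
    penalty for class rebalancing; a dual-branch transformer classifier with
    additive feature alignment and class-weighted cross-entropy; and
    confusion-matrix evaluation metrics. Neural components run on a small
    built-in reverse-mode automatic-differentiation engine supporting the
    double backpropagation the gradient penalty requires.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    EBImage,
    caret,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
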