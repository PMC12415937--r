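Package: caaquant
Title: Quantification of Vascular Amyloid-Beta Deposition from Confocal
    Microscopy with Hierarchical Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for quantifying fluorescent amyloid-beta
    deposition in cerebral arterioles and capillaries from multi-channel
    confocal image stacks. Classifies vasculature from Collagen IV and
    alpha-smooth-muscle-actin channels (complete-ring arteriole rule with
    area thresholds, dilation-and-subtraction capillary rule), detects
    amyloid aggregates by white top-hat and Mexican-hat (Laplacian of
    Gaussian) filtering with intensity thresholding, and summarises
    per-vessel wall coverage and per-aggregate size with intramural or
    extramural compartment assignment. Group comparisons use mixed models
    written from their likelihoods: a zero-inflated Beta GLMM for
    proportion-valued coverage with a point mass at zero and a Tweedie
    (compound Poisson-gamma) GLMM for skewed nonnegative aggregate sizes,
    both with nested mouse/image Gaussian random intercepts integrated out
    by Laplace approximation, Wald inference and estimated marginal means.
    A synthetic-data module generates both tabular studies drawn exactly
    from the fitted families and rendered image scenes with ground truth,
    so the full pipeline is testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    mgcv,
    glmmTMB,
    withr,
    optparse
Config/testthat/edition: 3
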