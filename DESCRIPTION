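Package: fundusgan
Title: Conditional Wasserstein GAN Synthesis of Retinal Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesis of retinal fundus images with a conditional Wasserstein
    generative adversarial network with gradient penalty (WGAN-GP). The
    generator is conditioned on a vessel-segmentation mask, two-scale lesion
    descriptor maps distilled from the input-gradient saliency of a diabetic
    retinopathy grader, and a noise vector; training adds perceptual and
    severity style-transfer losses on top of the adversarial objective.
    Includes a seeded procedural generator of toy fundus images with paired
    vessel masks, lesion masks and severity grades; a family of separable
    resampling kernels (nearest, bilinear, bicubic, Mitchell-Netravali,
    Lanczos-5, with optional antialiasing) used both for preprocessing and
    for the generator's decoder upsampling; and an evaluation suite computing
    Frechet Inception Distance, mean squared error and the structural
    similarity index.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jpeg,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
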