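Package: catintell
Title: Unpaired Degradation Synthesis and Restoration of Cataract Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage generative-adversarial framework for retinal fundus
    photographs degraded by cataract. A synthesis model learns, from unpaired
    sets of high-quality and cataract images, to impose realistic haze-like
    degradation on clean images; the resulting pairs train a restoration model
    that removes the degradation. Includes a U-shaped dense-convolution
    generator with exact parameter accounting, a window self-attention
    discriminator, pixel/perceptual/identity/adversarial losses, Adam training
    with warmup and cosine decay, a synthetic fundus phantom generator for
    fully self-contained experiments, and PSNR/SSIM evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
SystemRequirements: C++17
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
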