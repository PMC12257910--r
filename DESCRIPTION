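Package: nafmar
Title: Metal Artifact Reduction for CT via Neural Attenuation Fields
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Self-supervised metal artifact reduction (MAR) for fan-beam and
    cone-beam computed tomography. A neural attenuation field (a
    multi-resolution hash encoding feeding a small multilayer perceptron) is
    optimized on the metal-trace-masked projections of a single scan with a
    metal-aware weighted loss, rendered to an artifact-reduced volume, reduced
    to a three-class (air/soft-tissue/bone) prior image by k-means clustering,
    and used to inpaint the metal trace of the original sinogram by normalized
    per-row linear interpolation before filtered backprojection and metal
    reinsertion. The package also provides the physics substrate (ray-driven
    forward projector, filtered backprojection and FDK reconstruction), a
    polychromatic dental-phantom simulator with beam hardening and Poisson
    noise for generating paired clean/corrupted data, a linear-interpolation
    baseline, and masked PSNR/SSIM evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml,
    RNifti
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
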