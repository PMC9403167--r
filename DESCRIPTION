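Package: dotdiff
Title: Reference-Free Difference Imaging for Ultrasound-Guided Diffuse
    Optical Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, learning, and reconstruction tools for
    frequency-domain diffuse optical tomography (DOT) difference imaging
    of breast lesions.  Implements an analytic semi-infinite photon
    diffusion forward model with first-order Born perturbations, a
    synthetic scene generator emulating ultrasound-guided breast DOT
    (targets, chest wall, tissue heterogeneity), a multilayer perceptron
    that predicts the matched normalized perturbation from lesion-side
    measurements alone, Tikhonov-regularized conjugate-gradient image
    reconstruction on a dual mesh, multi-wavelength total-hemoglobin
    unmixing, and image-quality metrics (SSIM, target-to-artifact ratio,
    centroid distance).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
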