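Package: pwftomo
Title: Preconditioned Wirtinger Flow for Speckle-Based X-Ray Phase
    Microtomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-shot quantitative phase retrieval from X-ray speckle
    images under partial coherence, and tomographic reconstruction of the
    complex refractive index n = 1 - delta + i*beta. Implements a
    physics-based forward model (angular-spectrum free-space propagation
    through a diffuser, intensity blurring by a Gaussian intensity point
    spread function), a preconditioned, Tikhonov-regularized Wirtinger-flow
    solver with Nesterov acceleration, coherence calibration from reference
    speckle via the Siegert relation, diffuser transmission estimation by
    Wiener deconvolution, slice-wise Ram-Lak filtered back projection,
    Fourier shell correlation resolution analysis, and a self-consistent
    synthetic speckle-tomography simulator with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
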