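Package: poremri
Title: Pore Size Estimation from Spherical-Mean Diffusion-Relaxation MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unified diffusion-relaxation modelling of the spherical-mean
    (powder-average) MRI signal from water inside distributions of cylindrical
    pores, as used to estimate effective pore radii in axon-mimicking microfiber
    phantoms. Implements the van Gelderen Gaussian-phase-distribution model of
    restricted radial diffusion, the Neuman wide-pulse limit, the
    Brownstein-Tarr surface-relaxation link between intra-pore T2 and radius,
    numerical effective-radius estimation from measured radius distributions,
    surface-relaxivity calibration, spherical-mean pipelines for multi-TE and
    multi-b acquisitions, and a synthetic phantom simulator with Rician noise
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
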