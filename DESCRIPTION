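Package: lamellar
Title: Lamellar X-Ray Diffraction Analysis of Lipid Bilayer Phases
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for small- and wide-angle X-ray scattering
    (SAXS/WAXS) from multilamellar lipid vesicles: azimuthal integration of
    powder images, silver-behenate q-axis calibration, baseline estimation
    and Bragg peak fitting, indexing of lamellar diffraction orders into
    repeat-distance series, gel/fluid phase classification and coexistence
    detection, assembly of binary phase diagrams, Fourier reconstruction of
    relative electron density profiles with a truncation correction for the
    head-to-head distance, water-layer thickness, and gel-phase chain-tilt
    geometry.  Includes a forward diffraction simulator (Gaussian bilayer
    electron-density models, lamellar structure factors, Poisson counting
    noise, optional 2D powder images) that generates fully labelled
    synthetic data for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    minpack.lm,
    signal,
    yaml,
    jsonlite,
    tiff,
    withr,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
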