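Package: dmdlitho
Title: Job Planning, Calibration, Simulation and Quality Control for
    DMD Maskless Photolithography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational toolkit for maskless photolithography on a
    standard fluorescence microscope equipped with a digital micromirror
    device (DMD). Plans tiled exposure jobs from physical-unit raster
    designs (serpentine stage scans, per-field DMD frames), carries the
    optical and dosimetric arithmetic (pixel size, field of view, depth
    of focus, LED and DMD power models, energy dose, exposure-time
    inversion), calibrates spin-coated film thickness against spin speed
    (h = a/sqrt(RPM) + h0) including the multilayer consistency check,
    simulates prints into dose and cure maps, and quantifies printed
    line grids (probabilistic Hough detection, orientation and pitch
    statistics in micrometres). Runs entirely without hardware through a
    simulated microscope driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
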