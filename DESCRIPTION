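Package: nanoPSD
Title: Particle Detection and Morphometry for TEM Micrographs of
    Biogenic Nanoparticles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects and morphometrically characterizes nanoscale
    particles (roughly 2-12 nm equivalent circular diameter) in
    calibrated transmission electron micrographs of cyanobacteria.
    Implements percentile thresholding, connected-component particle
    extraction with hole inclusion and edge exclusion, per-particle
    size and shape descriptors (area, equivalent circular diameter,
    moment-fitted ellipse axes, maximum Feret diameter, reciprocal
    aspect ratio, Feret major axis ratio, six-class roundness
    classification), global and windowed particle size distributions,
    and cross-magnification quality-control tables. A synthetic
    micrograph generator with exact ground truth makes the whole
    pipeline testable without original micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    EBImage,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
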