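Package: gridcollim
Title: Design and Dosimetric Commissioning of Divergence-Matched Proton
    GRID Collimators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for designing, digitally modeling and
    dosimetrically commissioning a divergence-matched GRID (spatially
    fractionated) proton collimator. Generates the hexagonal aperture
    layout and per-hole divergent channel axes, builds a watertight STL
    mesh of the brass block, computes homogeneous placement transforms
    for arbitrary gantry/couch angles, creates divergence-matched
    optimization-cylinder planning structures and the scoring PTV,
    simulates GRID dose distributions with a synthetic pencil-beam
    raster engine, performs 2D gamma-index comparisons, reports SFRT
    dose metrics (Dxx, Dmean, PVDR, D90/D10, gEUD), models the
    measurement chain (ion-chamber arrays, partial-volume averaging,
    scintillator counts, radiochromic film calibration), and derives
    positional tolerances from Gaussian fits of gamma pass rate versus
    collimator offset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
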