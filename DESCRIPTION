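Package: velogrid
Title: Virtual-Grid Measurement of Velopharyngeal Motion from Stereo Endoscopic Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for four-dimensional measurement of soft-palate motion from
    calibrated stereo endoscopic video with a projected texture pattern. Produces
    per-frame range images via Tsai camera calibration, stereo rectification and
    sampling-insensitive scanline dynamic-programming matching; parameterizes a
    landmark-free quadrangle region of the soft palate with a virtual 5 x 5 grid
    (36 intersections); and quantifies motion by principal-component mode
    decomposition of the grid trajectories, centre-of-gravity shift magnitude,
    Mann-Whitney group comparison and two-class linear discriminant analysis.
    Includes a synthetic deforming-surface stereo renderer with analytic ground
    truth so the full pipeline can be exercised and validated without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    minpack.lm,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
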