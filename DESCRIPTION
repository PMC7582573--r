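Package: forceshadow
Title: Force Shadow Method for Vertical Ground Reaction Force Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online estimation of the total vertical ground reaction force
    (vGRF) from multi-segment body kinematics and its distribution over
    multiple simultaneous foot-contact regions, resolving the double-support
    indeterminacy without force plates. Segment centres of mass are projected
    along the ground reaction force vector onto the ground plane and summed
    into an elliptical-Gaussian "force shadow" surface; a triangulated 2D
    foot model is registered to each frame by landmark least squares, the
    shadow is integrated over anatomical foot regions by a midpoint
    (vertex-average) quadrature rule, and the raw distribution is refined by
    a quadratic foot-arch weight surface and a ramp-based hip-flexion
    balance model. Includes hyper-parameter calibration against reference
    load trajectories, pressure-plate footprint extraction and error
    metrics, and a synthetic-motion generator (sway, squat, gait) with
    static-equilibrium ground-truth loads and an emulated pressure plate so
    the full pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
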