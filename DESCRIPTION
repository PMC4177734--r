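Package: octguide
Title: Closed-Loop Simulation of OCT-Guided Laser Cochleostomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates optical-coherence-tomography (OCT) guided laser
    cochleostomy as a closed control loop running against a digital cochlea
    phantom. Provides a layered bone/endosteum/perilymph phantom with an
    OCT-like volume renderer (Beer-Lambert attenuation, speckle, axial and
    lateral point-spread functions), speckle reduction by history compounding
    and depth attenuation compensation, air-bone surface extraction and
    subsurface boundary segmentation with robust bicubic B-spline fitting,
    residual-thickness-driven pulse planning, tricubic B-spline cross-scanner
    calibration, landmark-based motion tracking, and the orchestrating
    scan-enhance-segment-plan-ablate loop with ground-truth evaluation of the
    final channel bottom against a user-defined stop surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
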