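Package: balicrawl
Title: Adhesive Crawling Locomotion of Hillstream Loaches: Simulation and
    Kinematic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models and analyses the two-sucker adhesive crawling gait of
    hillstream loaches (Balitoridae). Provides a quasi-static forward
    simulator of a crawling body built from two anisotropic suckers joined
    by an inextensible spine and driven by two antagonistic girdle
    actuators; a stick-slip ratcheting friction model of fin-ray adhesion
    with estimators for static and sliding friction coefficients from
    pulling-force traces; a midline kinematics pipeline (arc-length
    resampling to 101 points, 11 landmarks and 10 body segments, segment
    angles to the direction of travel, undulation amplitudes and
    instantaneous velocities); and gait-cycle analysis (fin-area state
    classification, cycle detection from right-pectoral-fin transitions,
    phase normalization to 20 increments, fin-muscle correlations). The
    simulator doubles as a synthetic-data generator for validating the
    analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
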