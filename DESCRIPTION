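Package: wristsim
Title: In Silico Physiologic Wrist Simulator with Hybrid and Cascade Tendon Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A fully in-silico physiologic wrist simulator: a two-degree-of-freedom,
    six-muscle tendon-driven wrist plant under gravity, driven through cyclic
    planar and complex motions (flexion-extension, radioulnar deviation, dart
    thrower's motion, circumduction) in three hand orientations by two control
    strategies that combine position and force feedback (hybrid control and
    cascade control with a quadratic muscle-stress-minimising force
    distribution). Includes tendon-excursion moment-arm estimation from passive
    sweeps, a synthetic specimen-cohort generator, and the accuracy,
    repeatability and nonparametric force-comparison analyses used to evaluate
    such simulators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
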