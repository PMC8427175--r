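Package: tailspin
Title: Inertial and Aerodynamic Tail Reorientation in Gliding Lizards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models mid-air reorientation by tail rotation in gliding
    lizards. Builds segmented rigid-body morphologies (prismatic torso,
    cylindrical legs, conical tail) with closed-form mass properties,
    simulates the free-floating body+tail system under conservation of
    angular momentum with optional aerodynamic restoring torques on body
    pitch and roll, runs planar constant-torque tail-swing protocols and
    tail-length scaling studies, searches cyclic two-axis tail trajectories
    with a genetic algorithm over cubic-spline collocation points, analyses
    landmark-tracked wind-tunnel kinematics (body/tail angles,
    cross-correlation lags, swing regression) with a matched synthetic-track
    generator, and provides quadratic-drag ballistics (drag coefficient,
    terminal velocity, fall distances) and torque scaling laws.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
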