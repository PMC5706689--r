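Package: kitecollide
Title: Spatial Collision-Probability Simulation for Tethered Tidal Kites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Transient three-dimensional (4D: space plus time) simulation of
    encounters between a marine animal, modelled as an ellipsoid in straight
    transit, and a tethered tidal kite flying a figure-of-eight trajectory.
    Ensembles over evenly spaced phase lags between animal and device motion
    turn the deterministic kinematics into a collision probability for every
    launch position on a cross-sectional grid. Provides exact minimum-distance
    computations between the animal ellipsoid and the device components
    (kite surface and tether capsule), a time-stepped collision detector with
    per-component bookkeeping, cross-section and swept-area probability
    metrics, time-step convergence studies, probability-map figures, and a
    command-line interface for reproducible sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    jsonlite,
    yaml,
    rlang,
    ggplot2,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
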