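Package: murmuration
Title: Topological Flocking Simulation and Internal Flock Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of three-dimensional starling flocks in
    which the number of topological (k-nearest) interaction partners differs
    per behaviour: collision avoidance acts on the k closest neighbours
    (typically a single one) while alignment and cohesion use the empirical
    topological range of 6-7 neighbours. Individuals fly with a cruise-speed
    controller and simplified banked-turn aerodynamics. The package also
    implements the standard internal-dynamics measurements for flock
    trajectories: neighbour stability (neighbour overlap) curves, diffusion
    in the centre-of-mass frame with anomalous-exponent power-law fitting,
    global and local polarization, and voxelised flock volume, together with
    preset flock-event experiments, a k-avoided sweep, volume-versus-size
    studies and separation-radius calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    arrow,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
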