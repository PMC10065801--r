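Package: escapegeom
Title: Geometric Modelling of Prey Escape Trajectories
Version: 0.1.0
Authors@R: person("escapegeom", "maintainers", email = "escapegeom@example.org",
    role = c("aut", "cre"))
Description: Implements a geometric model of prey escape trajectories (ETs)
    that accounts for the time the prey needs to turn and the endpoint of the
    predator's attack. The model ranks every reachable escape direction by the
    time margin between the prey's arrival at the edge of the safety zone and
    the predator's arrival at the same point. The package provides the full
    inference pipeline around the model: piecewise-linear (changepoint) fits
    of turn kinematics, rank-based calibration of predator attack distance and
    speed, a truncated-normal stochastic choice rule, Monte Carlo simulation
    of theoretical ET distributions, circular two-sample Kuiper testing,
    Gaussian-mixture mode counting, optimal/suboptimal choice analysis, a
    pursuit extension in which the predator can bend its approach path up to a
    minimum turning radius, and a synthetic-data generator emulating
    escape-response experiments on juvenile fish.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lme4,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
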