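Package: schoolsense
Title: Bayesian Optimal Sensor Placement for Flow-Sensing Schooling Swimmers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing surface sensor arrays on a fish-like follower
    swimmer that infers the size and relative position of a leading school from
    its own surface pressure gradients and shear stresses. Implements slender-body
    geometry and anguilliform midline kinematics, closed-loop schooling
    controllers, a reduced-fidelity two-dimensional incompressible Navier-Stokes
    solver with Brinkman penalization, a potential-flow surrogate generator for
    surface signals, a correlated Gaussian measurement model with exponential
    covariance and clustering penalty, nested Monte Carlo estimators of the
    expected Kullback-Leibler information gain for continuous and discrete
    unknowns, greedy sequential sensor placement, and grid-based posterior
    inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
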