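Package: reachgen
Title: Coordinate-Frame Models of Force-Field Generalization in Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and tools for studying how learned reaching dynamics
    generalize across arm configurations. Provides planar three-joint arm
    kinematics (forward/inverse kinematics, analytic Jacobians, minimum-jerk
    plans), velocity-dependent force fields rendered in extrinsic (Cartesian),
    intrinsic (joint-based) and object-centered coordinates, mechanical force
    channels, predicted channel-trial forces for each coordinate frame at a
    grid of test postures, constrained mixture and Gaussian-decay
    generalization model fitting with BIC comparison and leave-one-subject-out
    cross-validation, trajectory metrics (maximum perpendicular error, angular
    error, path length, baseline correlations), and a synthetic-cohort
    simulator that reproduces the trial structure of the underlying
    experiments so that every analysis stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
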