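Package: halorheo
Title: Brownian Dynamics and Microrheology Inversion for Toroidal Optical Traps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the overdamped Brownian dynamics of a micron-scale
    probe particle confined by a ring-shaped ("optical halo") optical trap in
    Newtonian and Jeffreys (viscoelastic) fluids, and inverts the resulting
    trajectory statistics to the fluid's complex shear modulus G*(omega).
    Provides analytic constitutive models and dimensionless groups, compiled
    Euler-Maruyama integrators (including a Markovian embedding of the
    exponential-memory generalized Langevin equation), torus-adapted mean
    squared displacement and position-autocorrelation estimators, the
    piecewise-linear unilateral Fourier transform of discrete compliance
    data, free and trapped generalized Stokes-Einstein inversions, and
    configuration-driven reproductions of the reference simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    withr,
    minpack.lm,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
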