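Package: conediff
Title: Brownian Dynamics of Spherocylindrical Particles in Narrowing Conical Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time overdamped Brownian dynamics of rigid
    spherocylindrical (capsule-shaped) particles diffusing through an
    axisymmetric conical channel with a reflecting wide end and an absorbing
    narrow end. One time step is a Gaussian translation attempt plus a
    Gaussian rotation attempt about a uniformly random axis, each rejected on
    collision with the channel wall; the rotational noise scale follows from
    energy equipartition via the particle's moment-of-inertia tensor. The
    package provides the collision geometry, the inertia model, a fast
    reproducible ensemble simulator with per-trajectory random-number
    substreams, and the full analysis toolchain: survivor-averaged mean
    squared displacement with anomalous-exponent fits, first-passage-time
    statistics, survival-probability decay fits, orientation and axial
    occupation histograms, and entropic-force estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
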