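Package: scalesym
Title: Detecting Scale Symmetry and Its Conserved Quantities in Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for deciding whether a dynamical system observed through a
    univariate (optionally planar) time series is scale-symmetric or merely
    scale-free.  The package implements a power-series family of
    scale-symmetric Lagrangians with a deviation exponent delta, the
    associated Noether conserved quantity, deterministic and stochastic
    simulators with known ground truth (inverse-cube and inverse-square
    central-force particles), and a variational-Laplace inversion with
    Bayesian model reduction that scores the scale-symmetric (delta = 0)
    model against the scale-free (delta != 0) alternative.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
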