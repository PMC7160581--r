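Package: lealpoly
Title: Multipoint Expansion Polynomials for Nonlinear Differential Equations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs Leal polynomials: single polynomials constrained to
    match prescribed values and derivatives at several expansion points
    simultaneously (confluent Hermite-type interpolants), with the derivative
    data generated directly from a nonlinear ordinary differential equation by
    the Taylor-series method. Includes truncated-series (jet) propagation for
    scalar high-order equations, coupled first-order systems and right-hand
    sides with sign discontinuities; least-squares polynomial modelling of
    unknown boundary derivatives over an intrinsic parameter; a registry of
    classic study problems (the Bratu/Gelfand problem, an isothermal porous
    catalyst reaction, a chronic myelogenous leukemia immune-dynamics system,
    the Thomas-Fermi equation, and a fifth-order equation with a discontinuous
    right-hand side); piecewise assembly; and mean-square convergence and
    error diagnostics over incremental-order sweeps.  Ill-conditioned
    confluent Vandermonde systems are solved in compensated double-double
    arithmetic (about 32 significant digits).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
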