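test_that("combustion-problem jets match the closed-form recursion", {
  phi <- 3.4
  x1 <- 0.9
  prob <- ode_problem(function(x, y, p) -p$phi * exp(y[[1]]), order = 2,
                      parameters = list(phi = phi))
  j <- taylor_derivatives(prob, 0, c(0, x1), 4)
  v <- as.numeric(j)
  expect_equal(v[3], -phi * exp(0), tolerance = 1e-14)
  expect_equal(v[4], -phi * x1 * exp(0), tolerance = 1e-14)
  expect_equal(v[5], (phi * exp(0) - x1^2) * phi * exp(0), tolerance = 1e-13)
  # nonzero boundary value too
  j2 <- taylor_derivatives(prob, 0, c(0.3, x1), 4)
  v2 <- as.numeric(j2)
  expect_equal(v2[3], -phi * exp(0.3), tolerance = 1e-13)
  expect_equal(v2[5], (phi * exp(0.3) - x1^2) * phi * exp(0.3),
               tolerance = 1e-12)
})

test_that("cubic-reaction jets match the closed-form fourth derivative", {
  phi <- 3
  prob <- ode_problem(function(x, y, p) p$phi^2 * y[[1]]^3, order = 2,
                      parameters = list(phi = phi))
  x0 <- 0.42; x1 <- 0.17
  v <- as.numeric(taylor_derivatives(prob, 0, c(x0, x1), 4))
  expect_equal(v[3], phi^2 * x0^3, tolerance = 1e-14)
  expect_equal(v[4], 3 * phi^2 * x0^2 * x1, tolerance = 1e-14)
  expect_equal(v[5], 3 * phi^2 * x0 * (phi^2 * x0^4 + 2 * x1^2),
               tolerance = 1e-13)
})

test_that("jets reproduce closed-form solutions to high order", {
  # u' = u, u(0) = 1: all derivatives 1
  p1 <- ode_problem(function(x, y, p) y[[1]], order = 1)
  expect_equal(as.numeric(taylor_derivatives(p1, 0, 1, 12)), rep(1, 13),
               tolerance = 1e-10)
  # u'' = -u, u(0) = 0, u'(0) = 1: sine cycle 0, 1, 0, -1, ...
  p2 <- ode_problem(function(x, y, p) -y[[1]], order = 2)
  v <- as.numeric(taylor_derivatives(p2, 0, c(0, 1), 12))
  expect_equal(v, rep(c(0, 1, 0, -1), length.out = 13), tolerance = 1e-12)
  # u' = u^2, u(0) = 1: u = 1/(1-x), k-th derivative k!
  p3 <- ode_problem(function(x, y, p) y[[1]]^2, order = 1)
  v3 <- as.numeric(taylor_derivatives(p3, 0, 1, 12))
  expect_equal(v3, factorial(0:12), tolerance = 1e-10)
})

test_that("seeds are preserved bitwise and bad seeds are rejected", {
  prob <- ode_problem(function(x, y, p) -y[[1]], order = 2)
  seed <- c(0.12345678901234567, -3.2109876543210987)
  v <- as.numeric(taylor_derivatives(prob, 0.3, seed, 6))
  expect_identical(v[1:2], seed)
  expect_error(taylor_derivatives(prob, 0, c(1), 4), "length 2")
})

test_that("coupled systems propagate jointly", {
  sys <- ode_problem(function(t, y, p) list(y[[2]], -y[[1]]),
                     kind = "system", components = c("u", "v"))
  j <- system_taylor_derivatives(sys, 0, c(0, 1), 10)
  expect_equal(as.numeric(j$u), rep(c(0, 1, 0, -1), length.out = 11),
               tolerance = 1e-12)
  expect_equal(as.numeric(j$v), rep(c(1, 0, -1, 0), length.out = 11),
               tolerance = 1e-12)
  expect_error(system_taylor_derivatives(sys, 0, c(1), 4), "one value per")
})

test_that("immune-dynamics first derivatives agree with a finite-difference oracle", {
  fx <- lp_fixtures()$cml
  prob <- ode_problem(
    function(t, y, p) {
      C <- y[[1]]; Te <- y[[2]]; Tn <- y[[3]]
      fr <- C / (C + p$eta)
      list(p$rc * C * log(p$Cmax / C) - p$dc * C - p$gc * C * Te,
           p$an * p$kn * Tn * fr + p$ae * Te * fr - p$de * Te - p$ge * C * Te,
           p$sn - p$dn * Tn - p$kn * Tn * fr)
    }, kind = "system", parameters = fx$parameters,
    components = c("C", "Te", "Tn"))
  jets <- system_taylor_derivatives(prob, 0, fx$initial, 2)
  # central finite difference of an independent integration, step 1e-4
  h <- 1e-4
  f <- function(t, y, pp) {
    p <- fx$parameters
    fr <- y[1] / (y[1] + p$eta)
    list(c(p$rc * y[1] * log(p$Cmax / y[1]) - p$dc * y[1] - p$gc * y[1] * y[2],
           p$an * p$kn * y[3] * fr + p$ae * y[2] * fr - p$de * y[2] -
             p$ge * y[1] * y[2],
           p$sn - p$dn * y[3] - p$kn * y[3] * fr))
  }
  # Richardson extrapolation: the fast effector response makes the third
  # time derivative of C large, so a plain difference at h carries a
  # visible truncation term
  cfd <- function(h) {
    fwd <- deSolve::ode(unname(fx$initial), c(0, h), f, NULL,
                        rtol = 1e-13, atol = 1e-13)
    bwd <- deSolve::ode(unname(fx$initial), c(0, -h), f, NULL,
                        rtol = 1e-13, atol = 1e-13)
    (fwd[2, 2] - bwd[2, 2]) / (2 * h)
  }
  fd <- as.numeric((4 * cfd(h / 2) - cfd(h)) / 3)
  expect_equal(as.numeric(jets$C)[2], fd, tolerance = 1e-5)
})

test_that("frozen sign propagation equals the smooth one-branch equation", {
  disc <- ode_problem(function(x, y, p) -5 * sgnp(x) * y[[1]] - y[[1]]^2 -
                        0.5 * x^3, order = 5)
  smooth <- ode_problem(function(x, y, p) -5 * y[[1]] - y[[1]]^2 - 0.5 * x^3,
                        order = 5)
  seed <- lp_fixtures()$discontinuity$node_p2
  expect_equal(as.numeric(taylor_derivatives(disc, 2, seed, 10)),
               as.numeric(taylor_derivatives(smooth, 2, seed, 10)),
               tolerance = 1e-14)
})

test_that("singular-equation jets reject non-positive bases", {
  tf <- ode_problem(function(x, y, p) y[[1]]^1.5 * x^(-0.5), order = 2)
  expect_error(taylor_derivatives(tf, 0, c(1, -1.588), 4), "positive")
  expect_error(taylor_derivatives(tf, 1, c(-0.5, 0.1), 4), "positive")
  # fine on a positive branch
  j <- taylor_derivatives(tf, 1, c(0.424, -0.274), 6)
  expect_equal(as.numeric(j)[3], 0.424^1.5, tolerance = 1e-13)
})

test_that("boundary jets inherit the two-point symmetry of the combustion problem", {
  phi <- 3.4
  m <- bratu_derivative_models()
  s <- predict(m$yp0, phi)
  prob <- ode_problem(function(x, y, p) -p$phi * exp(y[[1]]), order = 2,
                      parameters = list(phi = phi))
  X <- as.numeric(taylor_derivatives(prob, 0, c(0, s), 6))
  Y <- as.numeric(taylor_derivatives(prob, 1, c(0, -s), 6))
  even <- seq(1, 7, by = 2)
  odd <- seq(2, 6, by = 2)
  expect_equal(X[even], Y[even], tolerance = 1e-12)
  expect_equal(X[odd], -Y[odd], tolerance = 1e-12)
})
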