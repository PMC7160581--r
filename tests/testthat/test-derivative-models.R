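test_that("least squares recovers an exact polynomial relation", {
  phi <- seq(0, 2, by = 0.1)
  coef <- c(0.5, -1.2, 0.3, 2)
  ss <- boundary_sample_set(phi, naive_poly_eval(coef, phi))
  m <- fit_derivative_model(ss, 3)
  expect_equal(coef(m), coef, tolerance = 1e-10)
  expect_equal(m$degree, 3L)
})

test_that("noisy straight line matches the closed-form regression formulas", {
  set.seed(99)
  x <- seq(0, 1, length.out = 25)
  y <- 2.5 - 1.3 * x + rnorm(25, sd = 0.05)
  m <- fit_derivative_model(boundary_sample_set(x, y), 1)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  expect_equal(coef(m), c(intercept, slope), tolerance = 1e-12)
})

test_that("QR fit agrees with the normal-equations oracle on benign input", {
  set.seed(5)
  x <- seq(0.1, 2, length.out = 30)
  y <- sin(x)
  m <- fit_derivative_model(boundary_sample_set(x, y), 4)
  V <- outer(x, 0:4, `^`)
  normal <- solve(crossprod(V), crossprod(V, y))[, 1]
  expect_equal(coef(m), unname(normal), tolerance = 1e-8)
})

test_that("fitted coefficients are a local minimum of the squared error", {
  set.seed(2)
  x <- seq(0, 3, length.out = 20)
  ss <- boundary_sample_set(x, exp(-x) + rnorm(20, sd = 0.01))
  m <- fit_derivative_model(ss, 4)
  base <- model_objective(m, ss)
  for (j in seq_along(m$coefficients)) {
    for (d in c(-1e-6, 1e-6)) {
      m2 <- m
      m2$coefficients[j] <- m2$coefficients[j] + d
      expect_gt(model_objective(m2, ss), base)
    }
  }
})

test_that("objective is non-increasing in fit degree", {
  set.seed(13)
  x <- seq(0, 3, length.out = 25)
  ss <- boundary_sample_set(x, 1 / (1 + x^2) + rnorm(25, sd = 0.02))
  obj <- vapply(1:8, function(d)
    model_objective(fit_derivative_model(ss, d), ss), numeric(1))
  expect_true(all(diff(obj) <= 1e-12))
})

test_that("underdetermined fits are refused", {
  ss <- boundary_sample_set(c(0, 1, 2), c(1, 2, 3))
  expect_error(fit_derivative_model(ss, 3), "at least degree \\+ 1")
  expect_error(boundary_sample_set(c(0, 0, 1), c(1, 2, 3)),
               "strictly increasing")
})

test_that("the published combustion-slope models behave as printed", {
  m <- bratu_derivative_models()
  # constant term: the model value at phi = 0
  expect_equal(as.vector(predict(m$yp0, 0)), 0.01598501841, tolerance = 1e-12)
  # the two models are sign-flips of each other (up to printed rounding)
  phis <- seq(0, 3.4, by = 0.2)
  expect_equal(as.vector(predict(m$yp1, phis)), -as.vector(predict(m$yp0, phis)),
               tolerance = 5e-7)
  # model value at phi = 3.4 equals the linear coefficient of the
  # two-point reference polynomial
  expect_equal(as.vector(predict(m$yp0, 3.4)), 3.173281398, tolerance = 1e-5)
})

test_that("evaluation outside the fitted range is flagged as extrapolation", {
  m <- bratu_derivative_models()$yp0
  expect_warning(v <- predict(m, 5), "extrapolation")
  expect_true(attr(v, "extrapolated"))
  v2 <- predict(m, c(1, 2))
  expect_false(any(attr(v2, "extrapolated")))
})

test_that("shooting reproduces the published high-accuracy boundary slope", {
  ss <- generate_boundary_samples("bratu", 3.4)
  expect_equal(ss$value, 3.17473085207040, tolerance = 1e-10)
})

test_that("small-parameter limit of the combustion slope is phi/2", {
  ss <- generate_boundary_samples("bratu", c(0, 0.01))
  expect_identical(ss$value[1], 0)              # trivial solution at phi = 0
  expect_equal(ss$value[2] / 0.01, 0.5, tolerance = 5e-3)
})

test_that("catalyst shooting matches the first-integral quadrature oracle", {
  ss <- generate_boundary_samples("catalyst", 3, target = "z0")
  # oracle: z'^2 = (phi^2/2)(z^4 - z0^4); arc condition int dz/z' = 1
  len <- function(z0, phi = 3) {
    f <- function(t) {
      z <- z0 + t^2
      d <- z^4 - z0^4
      v <- 2 * t / sqrt((phi^2 / 2) * d)
      v[!is.finite(v)] <- 2 / (phi * sqrt(2 * z0^3))
      v
    }
    integrate(f, 0, sqrt(1 - z0), rel.tol = 1e-13, abs.tol = 1e-15,
              subdivisions = 2000L)$value
  }
  z0 <- uniroot(function(z) len(z) - 1, c(0.2, 0.8), tol = 1e-14)$root
  expect_equal(ss$value, z0, tolerance = 1e-9)
  # derivative at the far boundary via the same first integral
  sp <- generate_boundary_samples("catalyst", 3, target = "zp1")
  expect_equal(sp$value, sqrt(9 / 2 * (1 - z0^4)), tolerance = 1e-9)
})

test_that("singular-equation reference solver hits the published node values", {
  ref <- thomas_fermi_reference(c(1, 5))
  expect_equal(ref$y[1], 0.4240080520807056, tolerance = 1e-10)
  expect_equal(ref$y[2], 0.07880777925136990, tolerance = 1e-9)
  expect_equal(ref$yp[1], -0.2739890515933062, tolerance = 1e-8)
})
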