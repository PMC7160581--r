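lp_from_coef <- function(coef) {
  # wrap explicit coefficients as a leal_poly via exact sampling
  n <- length(coef)
  if (n == 1L) return(leal_poly(list(expansion_point(0, coef))))
  leal_poly(points_from_poly(coef, c(0, 1), c(n - 2L, 0L)))
}

test_that("successive-order metric is an exact mean-square integral", {
  p <- lp_from_coef(c(1, 2, 3))
  expect_identical(convergence_metric(p, p, 0, 1), 0)
  q <- lp_from_coef(c(1 + 0.25, 2, 3))   # differ by a constant
  expect_equal(convergence_metric(p, q, 0, 1), 0.25^2, tolerance = 1e-12)
  expect_error(convergence_metric(p, q, 1, 1), "b > a")
})

test_that("successive-order metric is symmetric, definite, and matches a naive oracle", {
  set.seed(21)
  for (i in 1:6) {
    a <- lp_from_coef(round(rnorm(sample(2:7, 1)), 2))
    b <- lp_from_coef(round(rnorm(sample(2:7, 1)), 2))
    m1 <- convergence_metric(a, b, -1, 2)
    expect_equal(m1, convergence_metric(b, a, -1, 2), tolerance = 1e-13)
    expect_equal(m1, naive_mean_square(coef(a), coef(b), -1, 2),
                 tolerance = 1e-10)
    expect_gte(m1, 0)
    expect_identical(convergence_metric(a, a, -1, 2), 0)
  }
})

test_that("error metric behaves on trivial references and scales quadratically", {
  lp <- lp_from_coef(c(0, 0, 1))           # x^2
  expect_lt(error_metric(function(x) x^2, lp, 0, 1), 1e-13)
  expect_equal(error_metric(function(x) x^2 + 1, lp, 0, 1), 1,
               tolerance = 1e-10)
  lp3 <- lp_from_coef(3 * c(0, 0, 1))
  e1 <- error_metric(function(x) sin(x), lp, 0, 1)
  e3 <- error_metric(function(x) 3 * sin(x), lp3, 0, 1)
  expect_equal(e3, 9 * e1, tolerance = 1e-8)
})

test_that("adaptive quadrature agrees with the closed form on polynomial references", {
  set.seed(31)
  for (i in 1:5) {
    co <- round(rnorm(6), 2)
    ref_lp <- lp_from_coef(co)
    lp <- lp_from_coef(round(rnorm(4), 2))
    exact <- error_metric(ref_lp, lp, 0, 2)
    quad <- error_metric(function(x) naive_poly_eval(co, x), lp, 0, 2)
    expect_equal(quad, exact, tolerance = 1e-12)
  }
})

test_that("pointwise error profile reports zeros for a perfect approximant", {
  lp <- lp_from_coef(c(1, -2, 0.5))
  prof <- error_profile(function(x) naive_poly_eval(c(1, -2, 0.5), x), lp,
                        seq(0, 1, by = 0.1))
  expect_true(all(prof$abs_error < 1e-14))
  expect_true(all(prof$rel_error < 1e-13))
})

test_that("combustion-problem error peaks midway between the expansion points", {
  lp <- build_case("bratu")
  ref <- case_reference("bratu")
  prof <- error_profile(ref$fun, lp, seq(0, 1, length.out = 101))
  peak <- prof$x[which.max(prof$abs_error)]
  expect_lt(abs(peak - 0.5), 0.06)
  expect_lt(max(prof$abs_error), 1e-2)
  expect_gt(max(prof$abs_error), 1e-5)
  # the same-degree single-point expansion is worse over the full interval
  yl <- taylor_reference("bratu", at = 0, order = 9)
  prof_t <- error_profile(ref$fun, yl, seq(0, 1, length.out = 101))
  expect_gt(max(prof_t$abs_error), max(prof$abs_error))
})

test_that("incremental-order sweeps show the decreasing trend", {
  qs <- lapply(1:10, function(q) c(q, q))
  sw <- run_sweep("bratu", qs)
  tr <- attr(sw, "trend")
  expect_lte(tr$last_error, tr$first_error)
  expect_lte(tr$spearman, -0.7)
  expect_true(is.na(sw$convergence[1]))
  expect_true(all(sw$convergence[-1] >= 0))
})

test_that("late-order successive differences fall below 1e-9", {
  qs <- lapply(7:10, function(q) c(q, q))
  sw <- run_sweep("bratu", qs, reference = FALSE)
  expect_lt(min(sw$convergence, na.rm = TRUE), 1e-9)
})

test_that("discontinuous-equation sweep converges by three orders of magnitude", {
  qs <- lapply(1:9, function(q) c(q, q))
  sw <- run_sweep("discontinuity", qs, reference = FALSE)
  expect_lt(sw$convergence[9], sw$convergence[2] * 1e-3)
})

test_that("a singular-equation segment sweep contracts without a reference", {
  qs <- lapply(0:6, function(q) c(0, q, q))
  sw <- run_sweep("thomas_fermi", qs, segment = 1, reference = FALSE)
  expect_lt(sw$convergence[7], sw$convergence[2])
})

test_that("degenerate and malformed sweeps are handled", {
  sw <- run_sweep("bratu", list(c(2, 2)), reference = FALSE)
  expect_identical(nrow(sw), 1L)
  expect_true(is.na(sw$convergence[1]))
  expect_error(run_sweep("bratu", list(c(1, 1), c(2, 3))), "at most 1")
  expect_error(run_sweep("bratu", list(c(1, 1), c(1, 3))), "at most 1")
})

test_that("immune-dynamics sweep error falls as orders grow", {
  qs <- list(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 2), c(0, 2, 2),
             c(0, 2, 3), c(0, 3, 3), c(0, 3, 4), c(0, 4, 4))
  sw <- run_sweep("cml", qs, component = "C")
  expect_lt(sw$error[9], sw$error[1])
})
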