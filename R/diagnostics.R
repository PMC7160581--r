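#' Mean-square difference between successive approximants
#'
#' The convergence diagnostic
#' \deqn{\frac{1}{b-a}\int_a^b (L_{q+1}(x) - L_q(x))^2\,dx,}
#' computed *exactly*: the integrand is a polynomial, so the coefficient
#' convolution is antidifferentiated in closed form (in double-double
#' arithmetic); numerical quadrature is used only as a cross-check in the
#' test suite.  The metric is symmetric in its two arguments and zero iff
#' the polynomials are equal.
#'
#' @param lp_a,lp_b two [leal_poly()] objects (successive orders).
#' @param a,b integration interval, `b > a` (typically the extreme
#'   expansion points).
#' @return Nonnegative scalar.
#' @export
convergence_metric <- function(lp_a, lp_b, a, b) {
  stopifnot(inherits(lp_a, "leal_poly"), inherits(lp_b, "leal_poly"))
  if (!(b > a)) stop("requires b > a", call. = FALSE)
  dd_mean_square_diff(lp_a$coef_hi, lp_a$coef_lo,
                      lp_b$coef_hi, lp_b$coef_lo, a, b)
}

#' Mean-square error against a reference solution
#'
#' \deqn{\frac{1}{b-a}\int_a^b (H(x) - L(x))^2\,dx} where \eqn{H} is a
#' reference (typically dense numerical) solution.  When the reference is
#' itself a polynomial the integral is evaluated exactly; otherwise by
#' adaptive quadrature.
#'
#' @param reference a vectorized function, or a [leal_poly()].
#' @param lp a [leal_poly()].
#' @param a,b interval with `b > a`.
#' @param abs.tol,rel.tol quadrature tolerances (ignored on the exact
#'   path).
#' @return Nonnegative scalar.
#' @export
error_metric <- function(reference, lp, a, b, abs.tol = 1e-14,
                         rel.tol = 1e-9) {
  stopifnot(inherits(lp, "leal_poly"))
  if (!(b > a)) stop("requires b > a", call. = FALSE)
  if (inherits(reference, "leal_poly")) {
    return(dd_mean_square_diff(reference$coef_hi, reference$coef_lo,
                               lp$coef_hi, lp$coef_lo, a, b))
  }
  stopifnot(is.function(reference))
  ig <- function(x) (reference(x) - predict(lp, x))^2
  q <- integrate(ig, a, b, abs.tol = abs.tol, rel.tol = rel.tol,
                 subdivisions = 500L, stop.on.error = FALSE)
  if (q$message != "OK" && q$abs.error > max(abs.tol, rel.tol * abs(q$value)))
    stop("quadrature did not converge (achieved absolute error ",
         format(q$abs.error, digits = 3), ")", call. = FALSE)
  q$value / (b - a)
}

check_increments <- function(orders) {
  # printed sweep sequences raise one entry at a time for three-point
  # plans and both entries together for symmetric two-point plans; accept
  # any step that increments one or more entries by exactly one
  for (i in seq_along(orders)[-1]) {
    d <- orders[[i]] - orders[[i - 1L]]
    if (!(all(d %in% c(0L, 1L)) && any(d == 1L)))
      stop("consecutive order vectors must differ by incrementing entries ",
           "by at most 1, with at least one increment (step ", i, ")",
           call. = FALSE)
  }
}

#' Incremental-order convergence and error sweep
#'
#' Builds the study-case approximant at each order vector of an
#' incremental sequence (consecutive vectors increment exactly one entry
#' by one) and records the successive-order convergence metric and the
#' error against the reference numerical solution.
#'
#' @param name case name, see [list_cases()].
#' @param orders list of order vectors.
#' @param interval integration interval; defaults to the span of the
#'   case's expansion points.
#' @param reference optional evaluator to use instead of
#'   [case_reference()]; `FALSE` skips the error column.
#' @param phi,component,segment passed to [build_case()].
#' @return A data frame of class `lp_sweep` with columns `step`, `orders`,
#'   `degree`, `convergence` (NA on the first step) and `error`; the
#'   trend summary (first/last error, Spearman rank correlation of step
#'   against log error) is attached as attribute `trend` and shown by
#'   `print`.
#' @export
run_sweep <- function(name, orders, interval = NULL, reference = NULL,
                      phi = NULL, component = c("C", "Te", "Tn"),
                      segment = NULL) {
  name <- match.arg(name, list_cases())
  component <- match.arg(component)
  stopifnot(is.list(orders), length(orders) >= 1L)
  check_increments(orders)
  if (is.null(interval)) {
    interval <- switch(name,
      bratu = c(0, 1), catalyst = c(0, 1),
      cml = range(lp_fixtures()$cml[[component]]$times),
      thomas_fermi = if (identical(segment, 2L) || identical(segment, 2))
        c(5, 25) else c(0, 5),
      discontinuity = c(-2, 2))
  }
  want_error <- !identical(reference, FALSE)
  H <- NULL
  if (want_error) {
    H <- if (is.function(reference)) reference
         else case_reference(name, phi = phi, component = component)$fun
  }
  polys <- lapply(orders, function(q)
    build_case(name, phi = phi, orders = q, component = component,
               segment = segment))
  n <- length(orders)
  conv <- rep(NA_real_, n)
  err <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L)
      conv[i] <- convergence_metric(polys[[i - 1L]], polys[[i]],
                                    interval[1], interval[2])
    if (want_error)
      err[i] <- error_metric(H, polys[[i]], interval[1], interval[2])
  }
  out <- data.frame(
    step = seq_len(n),
    orders = vapply(orders, function(q) paste(q, collapse = ","), character(1)),
    degree = vapply(polys, function(p) p$degree, integer(1)),
    convergence = conv,
    error = err
  )
  trend <- list()
  if (want_error && n > 1L) {
    trend$first_error <- err[1]
    trend$last_error <- err[n]
    pos <- err > 0
    trend$spearman <- if (sum(pos) > 2L)
      cor(seq_len(n)[pos], log(err[pos]), method = "spearman") else NA_real_
  }
  structure(out, trend = trend, interval = interval, case = name,
            class = c("lp_sweep", "data.frame"))
}

#' @export
print.lp_sweep <- function(x, ...) {
  cat("Incremental-order sweep:", attr(x, "case"), "on [",
      attr(x, "interval")[1], ",", attr(x, "interval")[2], "]\n")
  print.data.frame(x, digits = 4)
  tr <- attr(x, "trend")
  if (length(tr)) {
    cat(sprintf("error first -> last: %.3g -> %.3g; Spearman(step, log error) = %.2f\n",
                tr$first_error, tr$last_error, tr$spearman))
  }
  invisible(x)
}

#' Pointwise error profile
#'
#' Absolute and relative error of an approximant against a reference on a
#' grid; the relative error guards against vanishing references with a
#' tiny floor.
#'
#' @param reference vectorized function.
#' @param approximant a [leal_poly()], [leal_piecewise()], or function.
#' @param grid evaluation abscissae.
#' @param eps floor for the relative-error denominator.
#' @return Data frame with columns `x`, `reference`, `approx`,
#'   `abs_error`, `rel_error`.
#' @export
error_profile <- function(reference, approximant, grid, eps = 1e-30) {
  g <- as.numeric(grid)
  href <- reference(g)
  happ <- if (is.function(approximant)) approximant(g)
          else predict(approximant, g)
  ae <- abs(href - happ)
  data.frame(x = g, reference = href, approx = happ, abs_error = ae,
             rel_error = ae / pmax(abs(href), eps))
}
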