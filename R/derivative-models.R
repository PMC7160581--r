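#' Sample set of boundary derivatives over an intrinsic parameter
#'
#' Pairs of (parameter value, boundary derivative) used to fit a
#' [derivative model][fit_derivative_model].  Parameter values must be
#' strictly increasing.
#'
#' @param phi numeric vector of intrinsic-parameter values, strictly
#'   increasing.
#' @param value numeric vector of boundary-derivative values.
#' @param provenance free-text note on how the samples were produced
#'   (solver and tolerances).
#' @return A data frame of class `boundary_sample_set` with columns `phi`
#'   and `value`.
#' @export
boundary_sample_set <- function(phi, value, provenance = "") {
  stopifnot(length(phi) == length(value))
  if (is.unsorted(phi, strictly = TRUE))
    stop("phi values must be strictly increasing", call. = FALSE)
  structure(data.frame(phi = phi, value = value),
            provenance = provenance,
            class = c("boundary_sample_set", "data.frame"))
}

#' Least-squares polynomial model of a boundary derivative
#'
#' Fits a polynomial in the intrinsic parameter minimizing the sum of
#' squared residuals over the sample set.  The fit uses a QR
#' (orthogonal-factorization) solve of the Vandermonde design; monomial
#' least squares at degree 10-12 is ill-conditioned enough that normal
#' equations lose several digits, so the factorization route is the
#' implementation and the normal equations serve as an independent check
#' in the test suite.
#'
#' @param samples a [boundary_sample_set()] (or data frame with columns
#'   `phi`, `value`).
#' @param degree polynomial degree of the model.
#' @param target label of the boundary derivative being modelled.
#' @return Object of class `derivative_model`: `coefficients` (ascending
#'   powers), `degree`, `param_range` (the fitted range), `target`.
#' @seealso [predict.derivative_model()], [model_objective()]
#' @export
fit_derivative_model <- function(samples, degree, target = "") {
  degree <- as.integer(degree)
  stopifnot(degree >= 0L)
  phi <- samples$phi
  value <- samples$value
  if (length(phi) < degree + 1L)
    stop("need at least degree + 1 = ", degree + 1L, " samples", call. = FALSE)
  V <- outer(phi, 0:degree, `^`)
  qrv <- qr(V)
  if (qrv$rank < degree + 1L)
    stop("rank-deficient design: degree ", degree,
         " is not identifiable from these samples", call. = FALSE)
  coefs <- qr.coef(qrv, value)
  new_derivative_model(as.numeric(coefs), range(phi), target)
}

new_derivative_model <- function(coefficients, param_range, target = "") {
  structure(
    list(coefficients = coefficients, degree = length(coefficients) - 1L,
         param_range = as.numeric(param_range), target = target),
    class = "derivative_model"
  )
}

#' @export
coef.derivative_model <- function(object, ...) object$coefficients

#' Evaluate a boundary-derivative model
#'
#' Polynomial evaluation in the intrinsic parameter.  Evaluation outside
#' the fitted range is permitted but flagged: the result carries a logical
#' `extrapolated` attribute, and a warning is emitted.
#'
#' @param object a `derivative_model`.
#' @param phi parameter values at which to evaluate.
#' @param ... unused.
#' @return Numeric vector with attribute `extrapolated`.
#' @export
predict.derivative_model <- function(object, phi, ...) {
  phi <- as.numeric(phi)
  out <- vapply(phi, function(p) {
    r <- 0
    for (c in rev(object$coefficients)) r <- r * p + c
    r
  }, numeric(1))
  extra <- phi < object$param_range[1] | phi > object$param_range[2]
  if (any(extra))
    warning("evaluating the derivative model outside its fitted range [",
            object$param_range[1], ", ", object$param_range[2],
            "] is extrapolation", call. = FALSE)
  attr(out, "extrapolated") <- extra
  out
}

#' @export
print.derivative_model <- function(x, ...) {
  cat("Boundary-derivative model",
      if (nzchar(x$target)) paste0("for ", x$target) else "", "\n")
  cat("  degree ", x$degree, ", fitted on [", x$param_range[1], ", ",
      x$param_range[2], "]\n", sep = "")
  cat("  f(phi) =", poly_string(x$coefficients, var = "phi"), "\n")
  invisible(x)
}

#' Sum of squared residuals of a model on a sample set
#'
#' The objective the least-squares fit minimizes; exposed so optimality
#' can be probed directly (perturbing any fitted coefficient must increase
#' it).
#'
#' @param model a `derivative_model`.
#' @param samples a [boundary_sample_set()].
#' @export
model_objective <- function(model, samples) {
  pred <- suppressWarnings(predict(model, samples$phi))
  sum((samples$value - pred)^2)
}

#' The published boundary-slope models for the Bratu problem
#'
#' Degree-12 least-squares models of \eqn{y'(0)} and \eqn{y'(1)} as
#' functions of the Bratu parameter, fitted over \eqn{\Phi \in [0, 3.45]};
#' shipped verbatim as immutable reproduction fixtures.  The two models
#' are coefficient-wise sign flips of each other (the problem is symmetric
#' about \eqn{x = 1/2}).
#'
#' @return List with elements `yp0` and `yp1`, each a `derivative_model`.
#' @export
bratu_derivative_models <- function() {
  fx <- lp_fixtures()$bratu
  list(
    yp0 = new_derivative_model(fx$model_yp0, fx$model_range, "y'(0)"),
    yp1 = new_derivative_model(fx$model_yp1, fx$model_range, "y'(1)")
  )
}

#' The published boundary models for the porous-catalyst problem
#'
#' Degree-10 models of \eqn{z(0)} and \eqn{z'(1)} over the Thiele modulus.
#' The published coefficient lists are shipped verbatim, but note they are
#' internally inconsistent with the rest of the published record (see
#' [lp_fixtures()]); the catalyst case builder therefore defaults to the
#' published boundary *values* instead.
#'
#' @return List with elements `z0` and `zp1`, each a `derivative_model`.
#' @export
catalyst_derivative_models <- function() {
  fx <- lp_fixtures()$catalyst
  list(
    z0 = new_derivative_model(fx$model_z0, fx$model_range, "z(0)"),
    zp1 = new_derivative_model(fx$model_zp1, fx$model_range, "z'(1)")
  )
}

# -- numerical generation of boundary samples (shooting) ---------------------

bratu_shoot <- function(phi, rtol = 1e-12, atol = 1e-14) {
  # y'' = -phi exp(y), y(0) = 0, find y'(0) with y(1) = 0 (lower branch)
  if (phi == 0) return(0)
  f <- function(x, y, p) list(c(y[2], -phi * exp(y[1])))
  end <- function(s) {
    out <- deSolve::ode(c(0, s), c(0, 1), f, NULL, method = "ode45",
                        rtol = rtol, atol = atol)
    out[nrow(out), 2]
  }
  # y(1; s) is negative at s = 0, positive between the two branch slopes;
  # grow the bracket until it straddles the lower-branch root
  hi <- 0.5
  while (end(hi) < 0 && hi < 64) hi <- hi * 2
  if (end(hi) < 0)
    stop("Bratu shooting failed to bracket at phi = ", phi, call. = FALSE)
  stats::uniroot(end, c(0, hi), tol = 1e-15)$root
}

catalyst_endpoint <- function(a, phi, n = 3, rtol = 1e-12, atol = 1e-14) {
  f <- function(x, y, p) list(c(y[2], phi^2 * y[1]^n))
  out <- try(suppressWarnings(
    deSolve::ode(c(a, 0), c(0, 1), f, NULL, method = "ode45",
                 rtol = rtol, atol = atol, maxsteps = 50000)), silent = TRUE)
  if (inherits(out, "try-error")) return(c(Inf, Inf))
  v <- out[nrow(out), 2]
  if (is.na(v) || out[nrow(out), 1] < 1) return(c(Inf, Inf))
  c(v, out[nrow(out), 3])
}

catalyst_shoot <- function(phi, n = 3, rtol = 1e-12, atol = 1e-14) {
  # z'' = phi^2 z^n, z'(0) = 0, z(1) = 1: bisection on z(0) in (0, 1);
  # overshoot (or blow-up before x = 1) means z(0) too large
  if (phi == 0) return(c(z0 = 1, zp1 = 0))
  lo <- 0; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    v <- catalyst_endpoint(mid, phi, n, rtol, atol)[1]
    if (is.finite(v) && v < 1) lo <- mid else hi <- mid
  }
  z0 <- (lo + hi) / 2
  c(z0 = z0, zp1 = unname(catalyst_endpoint(z0, phi, n, rtol, atol)[2]))
}

#' Generate boundary-derivative samples by numerical BVP solution
#'
#' Solves the boundary-value problem over a grid of intrinsic-parameter
#' values by shooting over an adaptive embedded Runge-Kutta integrator and
#' records the requested boundary derivative.  At \eqn{\Phi = 0} both
#' problems have a closed-form trivial solution and the corresponding
#' exact value is used rather than a degenerate solve.
#'
#' @param problem `"bratu"` or `"catalyst"`.
#' @param grid increasing vector of parameter values.
#' @param target which boundary quantity: `"yp0"` (Bratu \eqn{y'(0)}),
#'   `"yp1"` (Bratu \eqn{y'(1)}), `"z0"` or `"zp1"` (catalyst).
#' @param rtol,atol integrator tolerances.
#' @return A [boundary_sample_set()]; non-convergent parameter values are
#'   dropped with a warning.
#' @export
generate_boundary_samples <- function(problem = c("bratu", "catalyst"),
                                      grid, target = NULL,
                                      rtol = 1e-12, atol = 1e-14) {
  problem <- match.arg(problem)
  if (is.null(target)) target <- if (problem == "bratu") "yp0" else "z0"
  vals <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    p <- grid[i]
    v <- try({
      if (problem == "bratu") {
        s <- bratu_shoot(p, rtol, atol)
        switch(target, yp0 = s, yp1 = -s,
               stop("unknown Bratu target ", target, call. = FALSE))
      } else {
        s <- catalyst_shoot(p, rtol = rtol, atol = atol)
        switch(target, z0 = unname(s["z0"]), zp1 = unname(s["zp1"]),
               stop("unknown catalyst target ", target, call. = FALSE))
      }
    }, silent = TRUE)
    if (inherits(v, "try-error")) {
      warning("shooting failed at phi = ", p, "; sample omitted",
              call. = FALSE)
    } else vals[i] <- v
  }
  keep <- !is.na(vals)
  boundary_sample_set(
    grid[keep], vals[keep],
    provenance = sprintf(
      "%s/%s via shooting over ode45, rtol=%g atol=%g", problem, target,
      rtol, atol)
  )
}
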