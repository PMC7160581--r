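#' Define an explicit-form ODE problem
#'
#' Describes a scalar ordinary differential equation in explicit form
#' \eqn{u^{(k)} = F(x, u, u', \dots, u^{(k-1)})} or a coupled first-order
#' system \eqn{u_i' = F_i(t, u_1, \dots, u_m)}.  The right-hand side is an
#' ordinary R function that must be evaluable on [taylor_series()]
#' arguments, which every composition of arithmetic, `exp`, `log`, `sqrt`,
#' `sin`, `cos`, real powers and [sgnp()] is.
#'
#' @param rhs for a scalar problem, `function(x, y, pars)` where `y` is a
#'   list of the solution and its derivatives `y[[1]] = u`, `y[[2]] = u'`,
#'   ..., up to order `order - 1`, returning the highest derivative
#'   \eqn{u^{(k)}}; for a system, `function(t, y, pars)` where `y` is a
#'   list of component values, returning a list of component derivatives.
#' @param order order \eqn{k} of the scalar equation; ignored for systems.
#' @param kind `"scalar"` or `"system"`.
#' @param parameters named list of intrinsic parameters passed as `pars`.
#' @param domain numeric length-2 interval on which the problem lives.
#' @param components character vector of component names (systems only).
#' @return An object of class `ode_problem`.
#' @examples
#' bratu <- ode_problem(function(x, y, p) -p$phi * exp(y[[1]]),
#'                      order = 2, parameters = list(phi = 3.4),
#'                      domain = c(0, 1))
#' taylor_derivatives(bratu, at = 0, seed = c(0, 3.17), up_to = 4)
#' @export
ode_problem <- function(rhs, order = 1L, kind = c("scalar", "system"),
                        parameters = list(), domain = c(-Inf, Inf),
                        components = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.function(rhs))
  if (kind == "scalar") {
    order <- as.integer(order)
    stopifnot(order >= 1L)
  } else {
    if (is.null(components))
      stop("a system problem needs component names", call. = FALSE)
    order <- 1L
  }
  structure(
    list(rhs = rhs, order = order, kind = kind, parameters = parameters,
         domain = as.numeric(domain), components = components),
    class = "ode_problem"
  )
}

#' @export
print.ode_problem <- function(x, ...) {
  if (x$kind == "scalar") {
    cat("<ode_problem> scalar, order", x$order, "\n")
  } else {
    cat("<ode_problem> system of", length(x$components), "components:",
        paste(x$components, collapse = ", "), "\n")
  }
  if (length(x$parameters))
    cat("  parameters:",
        paste(names(x$parameters), unlist(x$parameters), sep = " = ",
              collapse = ", "), "\n")
  invisible(x)
}

new_jet <- function(derivs, anchor) {
  structure(as.numeric(derivs), anchor = anchor, class = "ode_jet")
}

#' @export
print.ode_jet <- function(x, ...) {
  cat("<ode_jet> derivatives 0..", length(unclass(x)) - 1L,
      " at x = ", attr(x, "anchor"), "\n", sep = "")
  print(as.numeric(x))
  invisible(x)
}

# series of u^{(m)} to order j from Taylor coefficients tc of u
deriv_series <- function(tc, m, j) {
  i <- 0:j
  taylor_series(tc[i + m + 1L] * factorial(i + m) / (factorial(i) * factorial(m)))
}

#' Higher solution derivatives from the ODE (Taylor-series method)
#'
#' Given the value and the first `k - 1` derivatives of a solution of a
#' scalar order-`k` ODE at a point, computes derivatives up to order
#' `up_to` by repeated formal differentiation of the right-hand side,
#' implemented as truncated-series evaluation of `rhs`.  Derivatives
#' `0..k-1` of the result equal the seed exactly.
#'
#' The expansion point must lie inside a smooth branch of the right-hand
#' side: branch functions ([sgnp()]) are frozen at their value there, and
#' fractional powers require positive base values.
#'
#' @param problem an [ode_problem()] of kind `"scalar"`.
#' @param at expansion location.
#' @param seed numeric vector of length `order`: value and derivatives up
#'   to order `k - 1`.
#' @param up_to highest derivative order requested.
#' @return An `ode_jet`: numeric vector of derivatives `0..up_to` with the
#'   anchor as attribute.
#' @export
taylor_derivatives <- function(problem, at, seed, up_to) {
  stopifnot(inherits(problem, "ode_problem"))
  if (problem$kind != "scalar")
    stop("use system_taylor_derivatives() for systems", call. = FALSE)
  k <- problem$order
  if (length(seed) != k)
    stop("seed must supply value and derivatives up to order ", k - 1L,
         " (length ", k, ")", call. = FALSE)
  up_to <- as.integer(up_to)
  stopifnot(is.finite(at), up_to >= k - 1L)
  tc <- numeric(up_to + 1L)
  tc[seq_len(k)] <- seed / factorial(0:(k - 1L))
  if (up_to >= k) {
    for (j in 0:(up_to - k)) {
      x <- series_var(at, j)
      y <- lapply(0:(k - 1L), function(m) deriv_series(tc, m, j))
      f <- problem$rhs(x, y, problem$parameters)
      fc <- s_coef(as_series(f, j + 1L))
      tc[k + j + 1L] <- fc[j + 1L] * factorial(j) / factorial(k + j)
    }
  }
  new_jet(tc * factorial(0:up_to), at)
}

#' Joint higher derivatives for a coupled first-order system
#'
#' All components' Taylor coefficients are extended together so that the
#' coupling between equations is honored; the result for each component is
#' truncated at its own requested order.
#'
#' @param problem an [ode_problem()] of kind `"system"`.
#' @param at expansion location.
#' @param seed numeric vector: one value per component.
#' @param up_to integer, or integer vector with one entry per component.
#' @return Named list of `ode_jet` objects, one per component.
#' @export
system_taylor_derivatives <- function(problem, at, seed, up_to) {
  stopifnot(inherits(problem, "ode_problem"))
  if (problem$kind != "system")
    stop("use taylor_derivatives() for scalar problems", call. = FALSE)
  m <- length(problem$components)
  if (length(seed) != m)
    stop("seed must supply one value per component (", m, ")", call. = FALSE)
  if (length(up_to) == 1L) up_to <- rep(as.integer(up_to), m)
  stopifnot(length(up_to) == m, all(up_to >= 0L))
  top <- max(up_to)
  tc <- lapply(seed, function(v) { z <- numeric(top + 1L); z[1] <- v; z })
  if (top >= 1L) {
    for (j in 0:(top - 1L)) {
      x <- series_var(at, j)
      y <- lapply(tc, function(t) taylor_series(t[seq_len(j + 1L)]))
      f <- problem$rhs(x, y, problem$parameters)
      if (!is.list(f) || length(f) != m)
        stop("system rhs must return a list with one entry per component",
             call. = FALSE)
      for (i in seq_len(m)) {
        fc <- s_coef(as_series(f[[i]], j + 1L))
        tc[[i]][j + 2L] <- fc[j + 1L] / (j + 1L)
      }
    }
  }
  out <- lapply(seq_len(m), function(i) {
    n <- up_to[i]
    new_jet(tc[[i]][seq_len(n + 1L)] * factorial(0:n), at)
  })
  names(out) <- problem$components
  out
}
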