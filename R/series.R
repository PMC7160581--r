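#' Truncated Taylor series arithmetic
#'
#' A `taylor_series` holds the coefficients of a truncated power series
#' \eqn{u(x_0+h) = \sum_j u_j h^j} about an anchor point.  Arithmetic on
#' series objects (`+`, `-`, `*`, `/`, `^`, `exp`, `log`, `sqrt`, `sin`,
#' `cos`) propagates coefficients by the usual convolution and composition
#' recurrences, which is what lets an ODE right-hand side written as an
#' ordinary R function be evaluated on series arguments to obtain the
#' higher derivatives of a solution (Taylor-series method, a form of
#' Taylor-mode automatic differentiation).
#'
#' Coefficients are *Taylor* coefficients, i.e. the k-th derivative divided
#' by k!.  Conversion to raw derivatives is centralized in
#' [taylor_derivatives()].
#'
#' @param coef numeric vector of Taylor coefficients, constant term first.
#' @return An object of class `taylor_series`.
#' @seealso [series_var()], [series_const()], [sgnp()]
#' @export
taylor_series <- function(coef) {
  stopifnot(is.numeric(coef), length(coef) >= 1L)
  structure(list(coef = as.numeric(coef)), class = "taylor_series")
}

#' @describeIn taylor_series the independent variable \eqn{x = x_0 + h},
#'   truncated at `order`.
#' @param anchor expansion location \eqn{x_0}.
#' @param order truncation order (highest power of \eqn{h} retained).
#' @export
series_var <- function(anchor, order) {
  taylor_series(c(anchor, 1, rep(0, max(0L, order - 1L)))[seq_len(order + 1L)])
}

#' @describeIn taylor_series a constant as a series of the given order.
#' @param value the constant.
#' @export
series_const <- function(value, order) {
  taylor_series(c(value, rep(0, order)))
}

#' @export
print.taylor_series <- function(x, ...) {
  cat("<taylor_series> order", length(x$coef) - 1L, "\n")
  print(x$coef)
  invisible(x)
}

s_coef <- function(x) x$coef

# truncate both operands to the shorter length
s_align <- function(a, b) {
  n <- min(length(a), length(b))
  list(a = a[seq_len(n)], b = b[seq_len(n)], n = n)
}

s_mul <- function(a, b) {
  al <- s_align(a, b)
  n <- al$n
  out <- numeric(n)
  for (j in seq_len(n)) out[j] <- sum(al$a[seq_len(j)] * al$b[j:1])
  out
}

s_div <- function(a, b) {
  al <- s_align(a, b)
  if (al$b[1] == 0)
    stop("series division by a series with zero constant term", call. = FALSE)
  n <- al$n
  q <- numeric(n)
  q[1] <- al$a[1] / al$b[1]
  if (n > 1L) {
    for (j in 2:n) {
      q[j] <- (al$a[j] - sum(q[seq_len(j - 1L)] * al$b[j:2])) / al$b[1]
    }
  }
  q
}

# u^alpha for real alpha; requires u[1] > 0 unless alpha is a small
# non-negative integer (then repeated multiplication is used so that
# series with vanishing constant term, e.g. powers of (x - x0), work).
s_pow <- function(u, alpha) {
  if (alpha == round(alpha) && alpha >= 0 && alpha <= 64) {
    out <- c(1, rep(0, length(u) - 1L))
    for (i in seq_len(alpha)) out <- s_mul(out, u)
    return(out)
  }
  if (u[1] <= 0)
    stop("fractional power of a series requires a positive constant term ",
         "(value at the expansion point)", call. = FALSE)
  n <- length(u)
  w <- numeric(n)
  w[1] <- u[1]^alpha
  if (n > 1L) {
    for (m in seq_len(n - 1L)) {
      k <- seq_len(m)
      w[m + 1L] <- sum(((alpha + 1) * k / m - 1) * u[k + 1L] * w[m - k + 1L]) / u[1]
    }
  }
  w
}

s_exp <- function(u) {
  n <- length(u)
  w <- numeric(n)
  w[1] <- exp(u[1])
  if (n > 1L) {
    for (m in seq_len(n - 1L)) {
      k <- seq_len(m)
      w[m + 1L] <- sum(k * u[k + 1L] * w[m - k + 1L]) / m
    }
  }
  w
}

s_log <- function(u) {
  if (u[1] <= 0)
    stop("log of a series requires a positive constant term", call. = FALSE)
  n <- length(u)
  w <- numeric(n)
  w[1] <- log(u[1])
  if (n > 1L) {
    for (m in seq_len(n - 1L)) {
      k <- seq_len(m - 1L)
      acc <- if (m > 1L) sum(k * w[k + 1L] * u[m - k + 1L]) / m else 0
      w[m + 1L] <- (u[m + 1L] - acc) / u[1]
    }
  }
  w
}

s_sincos <- function(u) {
  n <- length(u)
  s <- numeric(n); c <- numeric(n)
  s[1] <- sin(u[1]); c[1] <- cos(u[1])
  if (n > 1L) {
    for (m in seq_len(n - 1L)) {
      k <- seq_len(m)
      s[m + 1L] <- sum(k * u[k + 1L] * c[m - k + 1L]) / m
      c[m + 1L] <- -sum(k * u[k + 1L] * s[m - k + 1L]) / m
    }
  }
  list(sin = s, cos = c)
}

as_series <- function(x, n) {
  if (inherits(x, "taylor_series")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(taylor_series(c(x, rep(0, n - 1L))))
  stop("cannot combine object of class ", class(x)[1L], " with a taylor_series",
       call. = FALSE)
}

#' @export
Ops.taylor_series <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(taylor_series(-s_coef(e1)))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for taylor_series", call. = FALSE)
  }
  n <- max(
    if (inherits(e1, "taylor_series")) length(s_coef(e1)) else 1L,
    if (inherits(e2, "taylor_series")) length(s_coef(e2)) else 1L
  )
  # scalar^series and series^scalar handled before promotion
  if (.Generic == "^" && is.numeric(e2) && length(e2) == 1L) {
    return(taylor_series(s_pow(s_coef(e1), e2)))
  }
  a <- s_coef(as_series(e1, n))
  b <- s_coef(as_series(e2, n))
  switch(.Generic,
    "+" = { al <- s_align(a, b); taylor_series(al$a + al$b) },
    "-" = { al <- s_align(a, b); taylor_series(al$a - al$b) },
    "*" = taylor_series(s_mul(a, b)),
    "/" = taylor_series(s_div(a, b)),
    "^" = taylor_series(s_exp(s_mul(s_log(a), b))),
    "==" = ,
    "!=" = ,
    "<" = ,
    ">" = ,
    "<=" = ,
    ">=" = stop("comparison of taylor_series objects is not defined; ",
                "use sgnp() for branch selection", call. = FALSE),
    stop(.Generic, " not defined for taylor_series", call. = FALSE)
  )
}

#' @export
Math.taylor_series <- function(x, ...) {
  u <- s_coef(x)
  switch(.Generic,
    exp  = taylor_series(s_exp(u)),
    log  = taylor_series(s_log(u)),
    sqrt = taylor_series(s_pow(u, 0.5)),
    sin  = taylor_series(s_sincos(u)$sin),
    cos  = taylor_series(s_sincos(u)$cos),
    stop(.Generic, " not supported for taylor_series", call. = FALSE)
  )
}

#' Sign function with the right-continuous convention
#'
#' Returns -1 for negative arguments and +1 for zero or positive arguments
#' (so `sgnp(0)` is `+1`).  On a truncated series the sign is *frozen* at
#' the sign of the value at the expansion point: during derivative
#' propagation across a piecewise-defined right-hand side, the branch is
#' locally constant, so `sgnp` of a series is a constant series.
#'
#' @param x numeric vector or a `taylor_series`.
#' @return Integer signs, or a constant `taylor_series`.
#' @export
sgnp <- function(x) UseMethod("sgnp")

#' @export
sgnp.default <- function(x) ifelse(x < 0, -1L, 1L)

#' @export
sgnp.taylor_series <- function(x) {
  v <- s_coef(x)
  taylor_series(c(if (v[1] < 0) -1 else 1, rep(0, length(v) - 1L)))
}
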