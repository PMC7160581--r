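#' Expansion point with prescribed value and derivatives
#'
#' A location together with the value and successive derivatives a
#' polynomial is required to match there.  The number of prescribed
#' derivatives is the *order* of the point; `values` has length
#' `order + 1` (value first, then first, second, ... derivatives).
#'
#' @param location finite expansion location.
#' @param values numeric vector: value then successive derivatives.
#' @param order nonnegative integer; defaults to `length(values) - 1`.
#' @return An object of class `expansion_point`.
#' @export
expansion_point <- function(location, values, order = length(values) - 1L) {
  order <- as.integer(order)
  if (!is.numeric(location) || length(location) != 1L || !is.finite(location))
    stop("location must be a single finite number", call. = FALSE)
  if (order < 0L)
    stop("order must be nonnegative", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) != order + 1L)
    stop("values must have length order + 1 (value then derivatives); got ",
         length(values), " for order ", order, call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  structure(list(location = location, order = order, values = values),
            class = "expansion_point")
}

#' @export
print.expansion_point <- function(x, ...) {
  cat("<expansion_point> x =", x$location, " order", x$order, "\n")
  print(x$values)
  invisible(x)
}

as_expansion_point <- function(p) {
  if (inherits(p, "expansion_point")) return(p)
  if (inherits(p, "ode_jet"))
    return(expansion_point(attr(p, "anchor"), as.numeric(p)))
  if (is.list(p) && !is.null(p$location) && !is.null(p$values))
    return(expansion_point(p$location, p$values,
                           if (is.null(p$order)) length(p$values) - 1L else p$order))
  stop("cannot interpret object of class ", class(p)[1L],
       " as an expansion point", call. = FALSE)
}

#' Degree of a multipoint expansion polynomial
#'
#' For expansion orders \eqn{q_a, q_b, \dots} at \eqn{M} distinct points
#' the interpolating polynomial has degree
#' \eqn{r = q_a + q_b + \dots + M - 1}: one condition per prescribed value
#' or derivative, hence \eqn{r + 1} coefficients.
#'
#' @param orders vector of nonnegative integer orders, one per point.
#' @return Integer degree.
#' @examples
#' lp_degree(c(4, 4))     # 9
#' lp_degree(c(0, 12, 12))  # 26
#' @export
lp_degree <- function(orders) {
  if (length(orders) == 0L)
    stop("at least one expansion order is required", call. = FALSE)
  orders <- as.integer(orders)
  if (any(is.na(orders)) || any(orders < 0L))
    stop("orders must be nonnegative integers", call. = FALSE)
  sum(orders) + length(orders) - 1L
}

check_points <- function(points) {
  points <- lapply(points, as_expansion_point)
  locs <- vapply(points, `[[`, numeric(1), "location")
  if (anyDuplicated(locs))
    stop("duplicate expansion locations; merge the conditions into a single ",
         "point of combined order instead", call. = FALSE)
  points
}

#' Condition system of a multipoint expansion polynomial
#'
#' Builds the confluent Vandermonde system whose solution is the monomial
#' coefficient vector: the row for condition (point \eqn{p}, derivative
#' \eqn{k}) holds \eqn{d^k x^i / dx^k} evaluated at the location of
#' \eqn{p}, for \eqn{i = 0..r}; the right-hand side entry is the
#' prescribed k-th derivative.  Rows are ordered by point (input order),
#' then by derivative order ascending, so serialized systems are
#' reproducible.
#'
#' This double-precision matrix is intended for inspection and testing;
#' [leal_poly()] performs the actual solve in extended precision.
#'
#' @param points list of [expansion_point()] objects (or coercible lists).
#' @return List with elements `matrix` ((r+1) x (r+1)) and `rhs` (length r+1).
#' @export
lp_condition_system <- function(points) {
  points <- check_points(points)
  r <- lp_degree(vapply(points, `[[`, integer(1), "order"))
  n <- r + 1L
  A <- matrix(0, n, n)
  b <- numeric(n)
  row <- 1L
  for (p in points) {
    for (k in 0:p$order) {
      i <- k:r
      fall <- factorial(i) / factorial(i - k)
      A[row, i + 1L] <- fall * p$location^(i - k)
      # 0^0 = 1 convention for the i = k column at location 0
      A[row, k + 1L] <- factorial(k)
      b[row] <- p$values[k + 1L]
      row <- row + 1L
    }
  }
  list(matrix = A, rhs = b)
}

#' Fit a multipoint expansion (Leal) polynomial
#'
#' Solves the interpolation conditions of [lp_condition_system()] for the
#' monomial coefficients.  The monomial basis is kept for output fidelity,
#' but the confluent Vandermonde systems involved are severely
#' ill-conditioned (a three-point degree-26 system is numerically singular
#' in 53-bit doubles), so the solve runs, by default, in compensated
#' double-double arithmetic (~32 significant decimal digits) on a
#' variable-scaled system \eqn{t = x/s}, \eqn{s = \max(1, \max|x_i|)};
#' coefficients are mapped back to the original variable afterwards.
#'
#' @param points list of [expansion_point()] objects (an [ode_jet] is
#'   accepted and converted).
#' @param precision working precision in significant decimal digits:
#'   `32` (default, double-double) or `16` (plain double, for comparison).
#' @return An object of class `leal_poly` with components
#'   \describe{
#'     \item{coefficients}{monomial coefficients `c0..cr`, ascending powers}
#'     \item{points}{the expansion points (provenance)}
#'     \item{precision_digits}{working precision used}
#'     \item{residual}{maximum relative residual of the (scaled) linear system}
#'   }
#'   Methods: [predict.leal_poly()], [coef.leal_poly()],
#'   [residuals.leal_poly()], `print`, `summary`, `plot`, and
#'   [lp_derivative()].
#' @examples
#' # degree-3 polynomial matching value and slope at 0 and at 1
#' lp <- leal_poly(list(expansion_point(0, c(0, 1)),
#'                      expansion_point(1, c(1, 0))))
#' coef(lp)
#' predict(lp, c(0, 0.5, 1))
#' @export
leal_poly <- function(points, precision = 32) {
  points <- check_points(points)
  orders <- vapply(points, `[[`, integer(1), "order")
  locs <- vapply(points, `[[`, numeric(1), "location")
  r <- lp_degree(orders)
  values <- unlist(lapply(points, `[[`, "values"))
  if (!precision %in% c(16, 32))
    stop("precision must be 16 or 32 significant digits", call. = FALSE)
  scale <- max(1, max(abs(locs)))
  if (precision == 32) {
    sol <- dd_solve_confluent(locs, orders, values, scale)
    if (isTRUE(sol$singular))
      stop("interpolation system is numerically singular at the requested ",
           "working precision; the expansion plan may be degenerate",
           call. = FALSE)
    hi <- sol$hi; lo <- sol$lo; residual <- sol$residual
  } else {
    sys <- lp_condition_system(points)
    co <- tryCatch(solve(sys$matrix, sys$rhs), error = function(e) NULL)
    if (is.null(co))
      stop("interpolation system is numerically singular in double ",
           "precision; retry with precision = 32", call. = FALSE)
    hi <- co; lo <- rep(0, length(co))
    residual <- max(abs(sys$matrix %*% co - sys$rhs) /
                      pmax(1, abs(sys$rhs)))
  }
  obj <- structure(
    list(coefficients = hi + lo, coef_hi = hi, coef_lo = lo,
         points = points, precision_digits = precision,
         residual = residual, degree = r),
    class = "leal_poly"
  )
  obj
}

#' @export
coef.leal_poly <- function(object, ...) object$coefficients

#' Evaluate a multipoint expansion polynomial
#'
#' Horner evaluation, carried out in double-double arithmetic so that the
#' heavy cancellation typical of high-degree monomial representations does
#' not erode accuracy.
#'
#' @param object a [leal_poly()].
#' @param x numeric vector of evaluation locations.
#' @param ... unused.
#' @return Numeric vector of polynomial values.
#' @export
predict.leal_poly <- function(object, x, ...) {
  dd_horner(object$coef_hi, object$coef_lo, as.numeric(x))
}

#' Derivative of a multipoint expansion polynomial
#'
#' @param lp a [leal_poly()].
#' @param k derivative order (`k = 0` returns the polynomial unchanged).
#' @return A `leal_poly` holding the k-th derivative's coefficients; its
#'   degree is `max(r - k, 0)`.  The provenance points are dropped.
#' @export
lp_derivative <- function(lp, k = 1L) {
  stopifnot(inherits(lp, "leal_poly"))
  k <- as.integer(k)
  stopifnot(k >= 0L)
  if (k == 0L) return(lp)
  d <- dd_poly_deriv(lp$coef_hi, lp$coef_lo, k)
  structure(
    list(coefficients = d$hi + d$lo, coef_hi = d$hi, coef_lo = d$lo,
         points = list(), precision_digits = lp$precision_digits,
         residual = NA_real_, degree = length(d$hi) - 1L),
    class = "leal_poly"
  )
}

#' Interpolation residuals of a fitted polynomial
#'
#' For every prescribed condition (point, derivative order) returns the
#' defect \eqn{d^k L/dx^k(x_p) - X_k}, evaluated in extended precision.
#'
#' @param object a [leal_poly()].
#' @param relative divide by `max(1, |prescribed value|)`?
#' @param ... unused.
#' @return Numeric vector, one entry per condition, named `"x<loc>:d<k>"`.
#' @export
residuals.leal_poly <- function(object, relative = FALSE, ...) {
  out <- numeric(0)
  nms <- character(0)
  for (p in object$points) {
    for (k in 0:p$order) {
      v <- dd_eval_deriv(object$coef_hi, object$coef_lo, p$location, k)
      d <- v - p$values[k + 1L]
      if (relative) d <- d / max(1, abs(p$values[k + 1L]))
      out <- c(out, d)
      nms <- c(nms, sprintf("x%g:d%d", p$location, k))
    }
  }
  names(out) <- nms
  out
}

poly_string <- function(coef, var = "x", digits = 10) {
  deg <- length(coef) - 1L
  terms <- character(0)
  for (i in 0:deg) {
    c <- coef[i + 1L]
    if (c == 0 && deg > 0L) next
    mono <- if (i == 0L) "" else if (i == 1L) var else paste0(var, "^", i)
    val <- sprintf("%.*g", digits, abs(c))
    term <- if (i == 0L) val else paste0(val, if (nzchar(mono)) "*" else "", mono)
    sign <- if (c < 0) "- " else if (length(terms)) "+ " else ""
    terms <- c(terms, paste0(sign, term))
  }
  if (!length(terms)) terms <- "0"
  paste(terms, collapse = " ")
}

#' @export
print.leal_poly <- function(x, digits = 10, ...) {
  cat("Multipoint expansion polynomial, degree", x$degree, "\n")
  if (length(x$points)) {
    locs <- vapply(x$points, `[[`, numeric(1), "location")
    ords <- vapply(x$points, `[[`, integer(1), "order")
    cat("  points: ", paste(sprintf("x=%g (order %d)", locs, ords),
                            collapse = ", "), "\n", sep = "")
  }
  cat("  working precision:", x$precision_digits, "digits")
  if (!is.na(x$residual))
    cat("; max relative residual:", format(x$residual, digits = 3))
  cat("\n  L(x) = ", poly_string(x$coefficients, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
summary.leal_poly <- function(object, ...) {
  res <- if (length(object$points)) residuals(object, relative = TRUE) else numeric(0)
  structure(list(lp = object, residuals = res), class = "summary.leal_poly")
}

#' @export
print.summary.leal_poly <- function(x, ...) {
  print(x$lp)
  if (length(x$residuals)) {
    cat("Interpolation conditions (relative defect):\n")
    print(signif(x$residuals, 3))
  }
  invisible(x)
}

#' @export
plot.leal_poly <- function(x, from = NULL, to = NULL, n = 201, ...) {
  if (is.null(from) || is.null(to)) {
    locs <- vapply(x$points, `[[`, numeric(1), "location")
    if (!length(locs)) locs <- c(-1, 1)
    from <- min(locs); to <- max(locs)
  }
  xs <- seq(from, to, length.out = n)
  plot(xs, predict(x, xs), type = "l", xlab = "x", ylab = "L(x)", ...)
  locs <- vapply(x$points, `[[`, numeric(1), "location")
  if (length(locs)) points(locs, predict(x, locs), pch = 19)
  invisible(x)
}
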