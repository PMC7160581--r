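#' Piecewise multipoint expansion approximation
#'
#' Assembles an ordered sequence of polynomial segments into a single
#' piecewise approximant.  Intervals are half-open `[lower, upper)`
#' except the last, which is closed; segments must be contiguous and
#' ascending.
#'
#' @param segments list of `list(lower, upper, poly)` entries, each `poly`
#'   a [leal_poly()].
#' @return An object of class `leal_piecewise`.
#' @examples
#' seg <- function(a, b, coef) {
#'   lp <- leal_poly(list(expansion_point(a, coef[1]),
#'                        expansion_point(b, sum(coef * c(1, b)))))
#'   list(lower = a, upper = b, poly = lp)
#' }
#' @export
leal_piecewise <- function(segments) {
  if (!length(segments))
    stop("at least one segment is required", call. = FALSE)
  lo <- vapply(segments, function(s) as.numeric(s$lower), numeric(1))
  hi <- vapply(segments, function(s) as.numeric(s$upper), numeric(1))
  if (any(hi <= lo))
    stop("each segment needs upper > lower", call. = FALSE)
  if (is.unsorted(lo, strictly = TRUE) && length(lo) > 1L)
    stop("segments must be in ascending order", call. = FALSE)
  if (length(segments) > 1L &&
      any(abs(hi[-length(hi)] - lo[-1]) > 1e-12 * pmax(1, abs(hi[-length(hi)]))))
    stop("segments must be contiguous: each upper bound must equal the next ",
         "lower bound", call. = FALSE)
  ok <- vapply(segments, function(s) inherits(s$poly, "leal_poly"), logical(1))
  if (!all(ok))
    stop("every segment needs a leal_poly in $poly", call. = FALSE)
  structure(list(segments = segments, lower = lo[1], upper = hi[length(hi)]),
            class = "leal_piecewise")
}

#' Evaluate a piecewise approximant
#'
#' Dispatches each abscissa to the half-open interval containing it (last
#' interval closed on the right).  Points outside the covered domain are a
#' domain error.
#'
#' @param object a [leal_piecewise()].
#' @param x numeric vector of evaluation locations.
#' @param ... unused.
#' @export
predict.leal_piecewise <- function(object, x, ...) {
  x <- as.numeric(x)
  if (any(x < object$lower | x > object$upper))
    stop("evaluation outside the covered domain [", object$lower, ", ",
         object$upper, "]", call. = FALSE)
  out <- numeric(length(x))
  nseg <- length(object$segments)
  for (i in seq_len(nseg)) {
    s <- object$segments[[i]]
    inside <- if (i < nseg) x >= s$lower & x < s$upper
              else x >= s$lower & x <= s$upper
    if (any(inside)) out[inside] <- predict(s$poly, x[inside])
  }
  out
}

#' @export
print.leal_piecewise <- function(x, ...) {
  cat("Piecewise multipoint expansion approximation,",
      length(x$segments), "segments on [", x$lower, ",", x$upper, "]\n")
  for (i in seq_along(x$segments)) {
    s <- x$segments[[i]]
    closed <- if (i == length(x$segments)) "]" else ")"
    cat(sprintf("  [%g, %g%s degree %d\n", s$lower, s$upper, closed,
                s$poly$degree))
  }
  invisible(x)
}

#' @export
plot.leal_piecewise <- function(x, n = 401, ...) {
  xs <- seq(x$lower, x$upper, length.out = n)
  plot(xs, predict(x, xs), type = "l", xlab = "x", ylab = "value", ...)
  invisible(x)
}
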