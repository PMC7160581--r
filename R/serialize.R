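#' Serialize a multipoint expansion polynomial to JSON
#'
#' Writes the record
#' `{"coefficients": [...], "points": [...], "precision_digits": n}` with
#' coefficients in ascending powers as *decimal strings* carrying the full
#' working precision (a double-double coefficient is printed to 33
#' significant digits, which a round trip through [read_lp_json()]
#' recovers to the same precision).
#'
#' @param lp a [leal_poly()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_lp_json <- function(lp, path) {
  stopifnot(inherits(lp, "leal_poly"))
  rec <- list(
    coefficients = as.list(dd_format(lp$coef_hi, lp$coef_lo, 33L)),
    points = lapply(lp$points, function(p)
      list(location = p$location, order = p$order,
           values = as.list(format(p$values, digits = 17)))),
    precision_digits = lp$precision_digits
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a multipoint expansion polynomial from JSON
#'
#' @param path file written by [write_lp_json()].
#' @return A [leal_poly()] object (points restored as provenance).
#' @export
read_lp_json <- function(path) {
  rec <- jsonlite::read_json(path)
  co <- dd_parse(vapply(rec$coefficients, as.character, character(1)))
  pts <- lapply(rec$points, function(p)
    expansion_point(p$location,
                    vapply(p$values, function(v) as.numeric(v), numeric(1)),
                    p$order))
  structure(
    list(coefficients = co$hi + co$lo, coef_hi = co$hi, coef_lo = co$lo,
         points = pts,
         precision_digits = as.numeric(rec$precision_digits),
         residual = NA_real_, degree = length(co$hi) - 1L),
    class = "leal_poly"
  )
}
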