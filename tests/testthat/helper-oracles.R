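# Shared oracles for the test suite.

# naive power-sum evaluation (independent of the Horner path)
naive_poly_eval <- function(coef, x) {
  vapply(x, function(xx) sum(coef * xx^(seq_along(coef) - 1L)), numeric(1))
}

# exact k-th derivative value of a polynomial given by coefficients
poly_deriv_value <- function(coef, x, k) {
  i <- seq_along(coef) - 1L
  keep <- i >= k
  sum(coef[keep] * factorial(i[keep]) / factorial(i[keep] - k) * x^(i[keep] - k))
}

# expansion points sampled exactly from a known polynomial
points_from_poly <- function(coef, locs, orders) {
  lapply(seq_along(locs), function(j) {
    vals <- vapply(0:orders[j], function(k) poly_deriv_value(coef, locs[j], k),
                   numeric(1))
    expansion_point(locs[j], vals)
  })
}

# closed-form mean-square integral of a polynomial difference, via plain
# double arithmetic (independent of the compiled path)
naive_mean_square <- function(p, q, a, b) {
  n <- max(length(p), length(q))
  d <- numeric(n)
  d[seq_along(p)] <- p
  d[seq_along(q)] <- d[seq_along(q)] - q
  sq <- rep(0, 2 * n - 1)
  for (i in seq_len(n))
    for (j in seq_len(n))
      sq[i + j - 1L] <- sq[i + j - 1L] + d[i] * d[j]
  anti <- sq / seq_along(sq)
  (sum(anti * b^seq_along(anti)) - sum(anti * a^seq_along(anti))) / (b - a)
}
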