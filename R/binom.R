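#' Exact two-sided binomial test, vectorized
#'
#' Computes the exact two-sided binomial p-value for observing `x` successes
#' in `n` trials at success probability `p0`, using the minimum-likelihood
#' rule: the p-value sums the probabilities of all outcomes whose probability
#' does not exceed that of the observed outcome (the same rule as
#' [stats::binom.test()]). Vectorized over sites; sites sharing `(n, p0)`
#' share one pmf evaluation, which makes population-scale matrices cheap.
#'
#' @param x Integer vector of success counts.
#' @param n Integer vector of trial counts (recycled against `x`).
#' @param p0 Null success probability, scalar or vector in (0, 1).
#' @return Numeric vector of p-values in (0, 1].
#' @export
binom_test_two_sided <- function(x, n, p0 = 0.5) {
  m <- max(length(x), length(n), length(p0))
  x <- rep_len(as.integer(x), m)
  n <- rep_len(as.integer(n), m)
  p0 <- rep_len(as.numeric(p0), m)
  if (any(p0 <= 0 | p0 >= 1)) abort("p0 must lie strictly in (0, 1)")
  if (any(x < 0 | x > n)) abort("x must lie in [0, n]")
  if (any(n < 1)) abort("n must be >= 1")

  out <- numeric(m)
  grp <- paste(n, p0)
  rel_tol <- 1 + 1e-7  # guard against ties broken by floating-point error
  for (g in unique(grp)) {
    idx <- which(grp == g)
    ni <- n[idx[1]]
    pi <- p0[idx[1]]
    d <- dbinom(0:ni, ni, pi)
    ord <- order(d)
    cs <- cumsum(d[ord])
    # number of outcomes with probability <= observed, via sorted pmf
    pos <- findInterval(d[x[idx] + 1L] * rel_tol, d[ord])
    out[idx] <- pmin(1, cs[pos])
  }
  out
}

#' One-sided upper binomial tail
#'
#' P(X >= x) for X ~ Binomial(n, p). Used for the genotype-warning noise
#' test.
#'
#' @inheritParams binom_test_two_sided
#' @param p Success probability.
#' @return Numeric vector of tail probabilities.
#' @export
binom_tail_upper <- function(x, n, p) {
  pbinom(x - 1, n, p, lower.tail = FALSE)
}
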