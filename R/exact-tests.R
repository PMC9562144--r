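# Exact tests used throughout the drive and motif analyses.
#
# Both tests use the "minimum-likelihood" (point-probability) two-sided
# convention: the two-sided p-value is the total null probability of all
# outcomes whose point probability does not exceed that of the observed
# outcome. This is the convention of classical spore-viability analysis
# tools (and of R's fisher.test / binom.test for these cases).

# relative tolerance when comparing point probabilities, so that outcomes
# tied with the observed one up to floating-point noise are included
.tie_tol <- 1e-12

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the exact two-sided p-value for independence in a 2x2
#' contingency table with fixed margins, as the sum of hypergeometric point
#' probabilities of all tables whose probability is less than or equal to
#' that of the observed table (point-probability rule). Probabilities are
#' evaluated in log space so large counts do not underflow.
#'
#' @param a,b,c,d Non-negative integer counts of the table
#'   \code{rbind(c(a, b), c(c, d))}, rows = groups, columns = outcomes.
#'   Alternatively \code{a} may be a 2x2 matrix and \code{b,c,d} omitted.
#' @return The two-sided p-value, a number in (0, 1].
#' @examples
#' fisher_exact_two_sided(9, 1, 2, 8)
#' fisher_exact_two_sided(matrix(c(17, 3, 14, 14), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  if (is.matrix(a)) {
    # note: the formal `c` is still a missing promise here, so base::c
    # must not be looked up by name until the counts are assigned
    stopifnot(length(dim(a)) == 2L, all(dim(a) == 2L))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("contingency table counts must be non-negative integers")
  if (sum(counts) == 0)
    stop("contingency table has zero grand total")
  m <- a + b      # row 1 total
  n <- c + d      # row 2 total
  k <- a + c      # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  x <- lo:hi
  logp <- stats::dhyper(x, m, n, k, log = TRUE)
  log_obs <- stats::dhyper(a, m, n, k, log = TRUE)
  p <- sum(exp(logp[logp <= log_obs + log1p(.tie_tol)]))
  min(1, max(p, exp(log_obs)))
}

#' Two-sided exact binomial test
#'
#' Exact two-sided goodness-of-fit test of \code{x} successes in \code{n}
#' Bernoulli trials against null success probability \code{p0}, using the
#' small-p-values (point-probability) method: the p-value sums the
#' Binomial(n, p0) probabilities of every outcome at most as probable as
#' the observed one.
#'
#' @param x Number of successes (0..n).
#' @param n Number of trials (> 0).
#' @param p0 Null success probability, strictly inside (0, 1). Default 0.5.
#' @return The two-sided p-value, a number in (0, 1].
#' @examples
#' exact_binomial_two_sided(0, 6)          # 2/64
#' exact_binomial_two_sided(60, 100, 0.5)
#' @export
exact_binomial_two_sided <- function(x, n, p0 = 0.5) {
  stopifnot(length(x) == 1, length(n) == 1, length(p0) == 1)
  if (!is.finite(n) || n != round(n) || n <= 0)
    stop("n must be a positive integer")
  if (!is.finite(x) || x != round(x) || x < 0 || x > n)
    stop("x must be an integer in [0, n]")
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("p0 must be strictly between 0 and 1")
  k <- 0:n
  logp <- stats::dbinom(k, n, p0, log = TRUE)
  log_obs <- stats::dbinom(x, n, p0, log = TRUE)
  p <- sum(exp(logp[logp <= log_obs + log1p(.tie_tol)]))
  min(1, max(p, exp(log_obs)))
}
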