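#' Two-sided beta-binomial outlier p-value
#'
#' Probability that a beta-binomial count is at least as extreme as the
#' observed split-read count under the cohort null: with
#' K ~ beta-binomial(n, mu, rho),
#' p = 2 * min(P(K <= k), P(K >= k)), capped at 1. rho = 0 reduces to the
#' exact binomial. Vectorized over observations; each element computes the
#' shorter tail by a stable probability-ratio recurrence and derives the
#' other from P(K <= k) + P(K >= k) = 1 + P(K = k).
#'
#' @param k Observed split-read count(s).
#' @param n Total informative coverage (k + m), `n >= 1`.
#' @param mu Null mean of theta, in (0, 1).
#' @param rho Overdispersion in `[0, 1)`; 0 means binomial.
#' @return Vector of two-sided p-values in (0, 1].
#' @export
betabinom_pvalue <- function(k, n, mu, rho) {
  len <- max(length(k), length(n), length(mu), length(rho))
  k <- rep_len(as.numeric(k), len)
  n <- rep_len(as.numeric(n), len)
  mu <- rep_len(as.numeric(mu), len)
  rho <- rep_len(as.numeric(rho), len)
  if (any(k < 0 | k > n, na.rm = TRUE)) abort("k must lie in [0, n]")
  if (any(mu <= 0 | mu >= 1, na.rm = TRUE)) {
    abort("null mean mu must lie strictly inside (0, 1)")
  }
  if (any(rho < 0 | rho >= 1, na.rm = TRUE)) abort("rho must lie in [0, 1)")
  p <- rep(NA_real_, len)
  ok <- !is.na(k) & !is.na(n) & !is.na(mu) & !is.na(rho)

  bin <- ok & rho == 0
  if (any(bin)) {
    lo <- pbinom(k[bin], n[bin], mu[bin])
    up <- pbinom(k[bin] - 1, n[bin], mu[bin], lower.tail = FALSE)
    p[bin] <- 2 * pmin(lo, up)
  }

  bb <- which(ok & rho > 0)
  if (length(bb) > 0) {
    kk <- k[bb]; nn <- n[bb]
    a <- mu[bb] * (1 - rho[bb]) / rho[bb]
    b <- (1 - mu[bb]) * (1 - rho[bb]) / rho[bb]
    f0 <- exp(lchoose(nn, kk) + lbeta(kk + a, nn - kk + b) - lbeta(a, b))
    low_short <- kk <= nn - kk
    steps <- ifelse(low_short, kk, nn - kk)
    f <- f0
    tot <- f0
    j <- kk
    alive <- steps > 0
    while (any(alive)) {
      ja <- j[alive]; na <- nn[alive]; aa <- a[alive]; ba <- b[alive]
      down <- low_short[alive]
      r <- ifelse(down,
                  ja * (na - ja + ba) / ((na - ja + 1) * (ja - 1 + aa)),
                  (na - ja) * (ja + aa) / ((ja + 1) * (na - ja - 1 + ba)))
      f[alive] <- f[alive] * r
      tot[alive] <- tot[alive] + f[alive]
      j[alive] <- ja + ifelse(down, -1, 1)
      steps[alive] <- steps[alive] - 1
      alive <- steps > 0
    }
    other <- 1 + f0 - tot
    lo <- ifelse(low_short, tot, other)
    up <- ifelse(low_short, other, tot)
    p[bb] <- 2 * pmin(lo, up)
  }
  pmin(pmax(p, .Machine$double.xmin), 1)
}
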