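test_that("degenerate cohorts fit a binomial null with clamped mean", {
  # identical theta across samples: no excess variance, rho = 0
  const <- one_site_counts(k = rep(18L, 20), m = rep(2L, 20))
  fit <- fit_site_nulls(compute_theta(const))
  expect_equal(fit$mu, 0.9)
  expect_equal(fit$rho, 0)
  expect_true(fit$testable)

  # all-zero splits: mu clamps to eps = 1/(2 * median coverage) > 0
  zero <- one_site_counts(k = rep(0L, 20), m = rep(20L, 20))
  fit0 <- fit_site_nulls(compute_theta(zero))
  expect_equal(fit0$mu, 1 / 40)
  expect_equal(fit0$rho, 0)

  # too few covered samples: untestable, not dropped
  few <- one_site_counts(k = rep(9L, 5), m = rep(1L, 5))
  fitf <- fit_site_nulls(compute_theta(few))
  expect_false(fitf$testable)
  expect_equal(fitf$n_fit, 5L)
})

test_that("moment fit recovers beta-binomial parameters", {
  # draws from the model via an independent generator (stats rbeta/rbinom)
  mu_true <- 0.8
  rho_true <- 0.05
  set.seed(301)
  for (rep in 1:5) {
    p <- rbeta(200, mu_true * (1 - rho_true) / rho_true,
               (1 - mu_true) * (1 - rho_true) / rho_true)
    k <- rbinom(200, 50, p)
    fit <- fit_site_nulls(compute_theta(one_site_counts(k, 50L - k)))
    expect_lt(abs(fit$mu - mu_true), 0.02)
    expect_lt(abs(fit$rho - rho_true), 0.03)
  }
})

test_that("two-sided p-values match exact tails and enumeration", {
  # closed-form binomial tail: all splits absent under mu = 0.5, n = 10
  expect_equal(betabinom_pvalue(0, 10, 0.5, 0), 2 * 0.5^10)
  # central observation is not extreme
  expect_gt(betabinom_pvalue(5, 10, 0.5, 0), 0.5)
  expect_gt(betabinom_pvalue(16, 20, 0.8, 0.1), 0.5)

  set.seed(302)
  for (i in 1:200) {
    n <- sample(1:100, 1)
    k <- sample(0:n, 1)
    mu <- runif(1, 0.01, 0.99)
    rho <- runif(1, 0, 0.3)
    expect_lt(abs(betabinom_pvalue(k, n, mu, rho) -
                    bb_pvalue_enum(k, n, mu, rho)), 1e-9)
  }
  expect_error(betabinom_pvalue(5, 10, 1, 0), "mu")
  expect_error(betabinom_pvalue(11, 10, 0.5, 0), "k")
})

test_that("null p-values are approximately uniform at high coverage", {
  set.seed(303)
  n <- 500
  mu <- 0.5
  rho <- 0.05
  p_lat <- rbeta(10000, mu * (1 - rho) / rho, (1 - mu) * (1 - rho) / rho)
  k <- rbinom(10000, n, p_lat)
  p <- betabinom_pvalue(k, n, mu, rho)
  expect_lt(ks_uniform_stat(p), 0.05)
})

test_that("BH adjustment matches the closed forms and a naive step-up", {
  rec <- tibble::tibble(sample_id = "S001", p = c(0.01, 0.02, 0.03))
  expect_equal(adjust_fdr(rec)$q, c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(tibble::tibble(sample_id = "a", p = 0.04))$q,
               0.04)
  expect_equal(adjust_fdr(tibble::tibble(sample_id = "a",
                                         p = rep(1, 5)))$q, rep(1, 5))

  set.seed(304)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    got <- adjust_fdr(tibble::tibble(sample_id = "s", p = p))$q
    expect_equal(got, bh_naive(p))
    expect_true(all(diff(got[order(p)]) >= -1e-12))
  }
})

test_that("per-sample FDR scope adjusts within each individual", {
  rec <- tibble::tibble(
    sample_id = rep(c("A", "B"), each = 3),
    p = c(0.01, 0.02, 0.03, 0.5, 0.6, 0.9)
  )
  got <- adjust_fdr(rec, scope = "sample")
  expect_equal(got$q[got$sample_id == "A"], c(0.03, 0.03, 0.03))
  expect_equal(got$q[got$sample_id == "B"], bh_naive(c(0.5, 0.6, 0.9)))
  pooled <- adjust_fdr(rec, scope = "cohort")
  expect_equal(pooled$q, bh_naive(rec$p))
})

test_that("empirical FDR of BH calling stays near the nominal level", {
  # 200 replicates of one individual's transcriptome-wide family:
  # 180 null tests, 20 strong signals
  set.seed(305)
  fdp <- replicate(200, {
    p <- c(runif(180), rbeta(20, 0.2, 40) * 1e-4)
    truth <- rep(c(FALSE, TRUE), c(180, 20))
    q <- adjust_fdr(tibble::tibble(sample_id = "s", p = p))$q
    rej <- q < 0.05
    if (any(rej)) sum(rej & !truth) / sum(rej) else 0
  })
  expect_lte(mean(fdp), 0.05 + 0.03)
})

test_that("significance needs both the q and the effect-size threshold", {
  rec <- tibble::tibble(
    q = c(0.01, 0.01, 0.2, NA),
    delta = c(-0.5, -0.1, -0.6, -0.9)
  )
  got <- call_outliers(rec)
  expect_equal(got$significant, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(got$direction[1], "retention")
  expect_equal(call_outliers(tibble::tibble(q = 0.01, delta = 0.4))$direction,
               "over-splicing")
})

test_that("leave-one-out scoring resists contamination by the outlier", {
  # 99 concordant samples plus one extreme retention outlier
  set.seed(306)
  k <- c(rbinom(99, 30, 0.97), 12)
  counts <- one_site_counts(k, 30L - k)
  th <- compute_theta(counts)
  nulls <- fit_site_nulls(th)
  loo <- score_outliers(th, nulls, leave_one_out = TRUE)
  full <- score_outliers(th, nulls, leave_one_out = FALSE)
  # the outlier's own p must be far smaller when it does not inflate
  # its null; the full-fit rho absorbs the outlier
  expect_lt(loo$p[100], full$p[100] / 10)
  expect_lt(loo$p[100], 1e-6)
  # null samples score almost identically either way
  expect_lt(max(abs(loo$p[1:99] - full$p[1:99])), 0.05)
})
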