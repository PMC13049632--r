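#' Fit per-site cohort nulls for theta
#'
#' For each splice site, fits a beta-binomial null for the split-read
#' fraction across the cohort by the method of moments: the null mean `mu`
#' is the coverage-weighted mean of theta, and the overdispersion `rho` is
#' the one-way ANOVA intraclass-correlation moment estimator on the binary
#' read outcomes grouped by sample, floored at 0 (so `rho = 0`, i.e. plain
#' binomial, whenever the empirical variance does not exceed the binomial
#' variance). `mu` is clamped to `[eps, 1 - eps]` with
#' `eps = 1 / (2 * median coverage)` so degenerate all-or-nothing sites
#' still yield a proper null. Sites with fewer than `min_fit_samples`
#' covered samples are marked untestable, never silently dropped.
#'
#' @param theta_tbl Output of [compute_theta()].
#' @param min_fit_samples Minimum samples with non-missing theta required
#'   to fit a site null (default 20).
#' @return One row per site: key columns, `n_fit`, `mu`, `rho`,
#'   `testable`.
#' @export
fit_site_nulls <- function(theta_tbl, min_fit_samples = 20) {
  site_cols <- c("chrom", "start", "end", "strand", "site_end")
  gid <- vctrs::vec_group_id(theta_tbl[site_cols])
  all_sites <- theta_tbl[!duplicated(gid), site_cols]
  all_sites <- all_sites[order(unique(gid)), , drop = FALSE]

  covered <- which(!is.na(theta_tbl$theta))
  out <- as_tibble(all_sites)
  out$n_fit <- 0L
  out$mu <- NA_real_
  out$rho <- NA_real_
  out$testable <- FALSE
  if (length(covered) > 0) {
    g <- gid[covered]
    n_i <- theta_tbl$n_total[covered]
    k_i <- theta_tbl$k_split[covered]
    sums <- rowsum(
      cbind(m = 1, n = n_i, k = k_i, n2 = n_i^2,
            s2 = k_i^2 / n_i, w = k_i * (n_i - k_i) / n_i),
      g
    )
    rows <- as.integer(rownames(sums))
    med <- tapply(n_i, g, stats::median)
    mu_raw <- sums[, "k"] / sums[, "n"]
    eps <- 1 / (2 * med)
    ss_between <- pmax(sums[, "s2"] - sums[, "n"] * mu_raw^2, 0)
    out$n_fit[rows] <- as.integer(sums[, "m"])
    out$mu[rows] <- pmin(pmax(mu_raw, eps), 1 - eps)
    out$rho[rows] <- icc_moment_estimate(sums[, "m"], sums[, "n"],
                                         ss_between, sums[, "w"],
                                         sums[, "n2"])
    out$testable[rows] <- sums[, "m"] >= min_fit_samples
  }
  out
}

# Fleiss one-way ANOVA intraclass-correlation estimator on binary splice
# outcomes clustered by sample; vectorized over sites.
icc_moment_estimate <- function(m, n_total, ss_between, ss_within,
                                sum_n_sq) {
  bms <- ss_between / pmax(m - 1, 1)
  wms <- ss_within / pmax(n_total - m, 1)
  n0 <- (n_total - sum_n_sq / n_total) / pmax(m - 1, 1)
  rho <- (bms - wms) / (bms + (n0 - 1) * wms)
  rho[!is.finite(rho)] <- 0
  pmin(pmax(rho, 0), 0.99)
}

#' Score observations against fitted site nulls
#'
#' Computes, for every covered observation at a testable site, the signed
#' deviation `delta = theta - mu` and a two-sided beta-binomial p-value
#' ([betabinom_pvalue()]). Negative delta means less splicing than the
#' cohort expects, i.e. retention.
#'
#' By default each observation is scored against a leave-one-out null:
#' the site's moment fit recomputed from closed-form downdated sums with
#' the tested sample excluded. A genuine outlier otherwise contaminates
#' its own null -- a single extreme sample in a 100-sample cohort inflates
#' the site's moment overdispersion enough to mask itself -- while under
#' the null the leave-one-out fit is essentially identical to the full
#' fit. `leave_one_out = FALSE` scores against the full-cohort fit from
#' `nulls`.
#'
#' @param theta_tbl Output of [compute_theta()].
#' @param nulls Output of [fit_site_nulls()] (supplies testability and
#'   reporting; the full-cohort `mu`/`rho` are used when
#'   `leave_one_out = FALSE`).
#' @param leave_one_out Logical, default `TRUE`.
#' @return Per-(sample, site) tibble with `mu`, `rho`, `delta`, `p`
#'   (`NA` where theta is missing or the site is untestable).
#' @export
score_outliers <- function(theta_tbl, nulls, leave_one_out = TRUE) {
  site_cols <- c("chrom", "start", "end", "strand", "site_end")
  row_site <- vctrs::vec_match(theta_tbl[site_cols], nulls[site_cols])
  scored <- theta_tbl
  scored$mu <- nulls$mu[row_site]
  scored$rho <- nulls$rho[row_site]
  scored$testable <- nulls$testable[row_site]

  if (leave_one_out) {
    gid <- vctrs::vec_group_id(theta_tbl[site_cols])
    covered <- which(!is.na(theta_tbl$theta))
    g <- gid[covered]
    n_i <- theta_tbl$n_total[covered]
    k_i <- theta_tbl$k_split[covered]
    sums <- rowsum(
      cbind(m = 1, n = n_i, k = k_i, n2 = n_i^2,
            s2 = k_i^2 / n_i, w = k_i * (n_i - k_i) / n_i),
      g
    )
    # median site coverage sets the clamp floor eps = 1/(2*median cov)
    med <- tapply(n_i, g, stats::median)
    at <- match(g, as.integer(rownames(sums)))
    m_l <- sums[at, "m"] - 1
    n_l <- sums[at, "n"] - n_i
    k_l <- sums[at, "k"] - k_i
    mu_raw <- k_l / n_l
    eps <- 1 / (2 * med[at])
    ss_b <- pmax(sums[at, "s2"] - k_i^2 / n_i - n_l * mu_raw^2, 0)
    ss_w <- sums[at, "w"] - k_i * (n_i - k_i) / n_i
    sq_l <- sums[at, "n2"] - n_i^2
    scored$mu[covered] <- pmin(pmax(mu_raw, eps), 1 - eps)
    scored$rho[covered] <- icc_moment_estimate(m_l, n_l, ss_b, ss_w, sq_l)
  }
  scored$delta <- scored$theta - scored$mu
  scored$p <- NA_real_
  idx <- which(!is.na(scored$theta) & scored$testable &
                 !is.na(scored$mu) & is.finite(scored$mu))
  if (length(idx) > 0) {
    scored$p[idx] <- betabinom_pvalue(
      scored$k_split[idx], scored$n_total[idx],
      scored$mu[idx], scored$rho[idx]
    )
  }
  as_tibble(scored)
}

#' Benjamini-Hochberg adjustment of outlier p-values
#'
#' Step-up BH q-values over all tested splice sites, by default within
#' each sample (transcriptome-wide correction per individual, matching
#' per-individual outlier counting). `scope = "cohort"` pools every
#' (sample, site) test into one family instead.
#'
#' @param records Scored tibble from [score_outliers()].
#' @param scope `"sample"` (default) or `"cohort"`.
#' @return `records` with a `q` column (`NA` where `p` is `NA`).
#' @export
adjust_fdr <- function(records, scope = c("sample", "cohort")) {
  scope <- match.arg(scope)
  records <- as_tibble(records)
  if (scope == "sample") {
    records %>%
      group_by(.data$sample_id) %>%
      mutate(q = p.adjust(.data$p, method = "BH")) %>%
      ungroup()
  } else {
    mutate(records, q = p.adjust(.data$p, method = "BH"))
  }
}

#' Call significant theta outliers
#'
#' Applies the significance rule: `q < q_max` and `|delta| >= delta_min`
#' (defaults q < 0.05 and |delta| >= 0.3). All records are returned with
#' flags; `direction` is `"retention"` for delta < 0 and `"over-splicing"`
#' otherwise, so retention-only counting stays available downstream.
#'
#' @param records Collapsed per-(sample, intron) tibble carrying `q` and
#'   `delta` (see [collapse_to_intron()]), or any tibble with those
#'   columns.
#' @param q_max FDR threshold (default 0.05).
#' @param delta_min Minimum absolute deviation of theta (default 0.3).
#' @return `records` with `significant` and `direction` columns.
#' @export
call_outliers <- function(records, q_max = 0.05, delta_min = 0.3) {
  records <- as_tibble(records)
  records %>%
    mutate(
      significant = !is.na(.data$q) & .data$q < q_max &
        abs(.data$delta) >= delta_min,
      direction = if_else(.data$delta < 0, "retention", "over-splicing")
    )
}
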