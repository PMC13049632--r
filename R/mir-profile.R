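#' Count minor intron retention outliers per individual
#'
#' Given significant outlier calls already restricted to minor introns
#' (see [restrict_to_minor()]), counts per sample the number of MIR
#' outliers and the number of distinct minor intron-containing genes
#' (MIGs) among them. Samples without any call appear with zero counts so
#' cohort statistics cover the whole cohort.
#'
#' @param calls Tibble of significant minor-intron calls with `sample_id`
#'   and `gene_id` columns.
#' @param samples Tibble with one row per cohort sample: `sample_id`,
#'   `tissue`.
#' @param direction Count calls in both directions (default, matching the
#'   absolute effect-size rule) or retention-direction only.
#' @return Tibble (`sample_id`, `tissue`, `n_mir_outliers`, `n_migs`).
#' @export
count_mir_outliers <- function(calls, samples,
                               direction = c("both", "retention")) {
  direction <- match.arg(direction)
  calls <- as_tibble(calls)
  samples <- distinct(as_tibble(samples), .data$sample_id, .data$tissue)
  if (anyDuplicated(samples$sample_id)) {
    abort("a sample_id maps to more than one tissue")
  }
  if (direction == "retention" && nrow(calls) > 0) {
    calls <- filter(calls, .data$direction == "retention")
  }
  per_sample <- calls %>%
    group_by(.data$sample_id) %>%
    summarise(
      n_mir_outliers = dplyr::n(),
      n_migs = n_distinct(.data$gene_id),
      .groups = "drop"
    )
  samples %>%
    left_join(per_sample, by = "sample_id") %>%
    mutate(
      n_mir_outliers = if_else(is.na(.data$n_mir_outliers), 0L,
                               .data$n_mir_outliers),
      n_migs = if_else(is.na(.data$n_migs), 0L, .data$n_migs)
    )
}

#' Tissue-stratified cohort summary of MIR counts
#'
#' Mean, sample standard deviation (n - 1 denominator), median and
#' quartiles (linear interpolation on sorted values, the R default
#' quantile type) of the per-individual MIR-outlier counts, computed
#' within each tissue stratum. Strata are never pooled.
#'
#' @param profiles Output of [count_mir_outliers()].
#' @return Tibble (`tissue`, `n_samples`, `mean`, `sd`, `median`,
#'   `iqr_low`, `iqr_high`).
#' @export
cohort_summary <- function(profiles) {
  profiles <- as_tibble(profiles)
  sizes <- count(profiles, .data$tissue)
  if (any(sizes$n < 2)) {
    abort(paste0("cannot compute SD: tissue stratum '",
                 sizes$tissue[sizes$n < 2][1], "' has fewer than 2 samples"))
  }
  profiles %>%
    group_by(.data$tissue) %>%
    summarise(
      n_samples = dplyr::n(),
      mean = mean(.data$n_mir_outliers),
      sd = sd(.data$n_mir_outliers),
      median = stats::median(.data$n_mir_outliers),
      iqr_low = unname(quantile(.data$n_mir_outliers, 0.25, type = 7)),
      iqr_high = unname(quantile(.data$n_mir_outliers, 0.75, type = 7)),
      .groups = "drop"
    )
}

#' Flag individuals with an excess of minor intron retention
#'
#' An individual has an excess of MIR when their MIR-outlier count exceeds
#' the mean of their own tissue stratum by more than `sd_multiplier`
#' standard deviations. Z scores are computed against the stratum as
#' observed (candidates are not held out). When a stratum SD is zero the
#' Z score is undefined (reported `NA`) and no sample in it is flagged.
#'
#' @param profiles Output of [count_mir_outliers()].
#' @param sd_multiplier Number of SDs above the mean (default 2).
#' @return `profiles` with `z` and `excess` columns.
#' @export
flag_excess <- function(profiles, sd_multiplier = 2) {
  stats_tbl <- cohort_summary(profiles)
  profiles %>%
    left_join(select(stats_tbl, "tissue", "mean", "sd"), by = "tissue") %>%
    mutate(
      z = if_else(.data$sd > 0,
                  (.data$n_mir_outliers - .data$mean) / .data$sd, NA_real_),
      excess = .data$sd > 0 &
        .data$n_mir_outliers > .data$mean + sd_multiplier * .data$sd
    ) %>%
    select(-"mean", -"sd")
}

#' Rank-ordered scatter data for MIR profiles
#'
#' Per tissue, orders individuals by their MIR-outlier count and assigns
#' x-axis ranks, mirroring cohort outlier scatter plots (one dot per
#' individual, y = count).
#'
#' @param profiles Output of [flag_excess()] or [count_mir_outliers()].
#' @return `profiles` with a `rank` column, sorted within tissue.
#' @export
rank_mir_profiles <- function(profiles) {
  profiles %>%
    group_by(.data$tissue) %>%
    arrange(.data$n_mir_outliers, .data$sample_id, .by_group = TRUE) %>%
    mutate(rank = row_number()) %>%
    ungroup()
}
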