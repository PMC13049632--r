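#' Rank-ordered MIR outlier scatter
#'
#' One dot per individual, ordered within tissue by the number of
#' significant minor intron retention outliers; individuals flagged with
#' an excess of MIR are highlighted. Mirrors the per-cohort outlier
#' scatter used to spot minor spliceopathy candidates.
#'
#' @param profiles Profile tibble from [flag_excess()] /
#'   [rank_mir_profiles()] (a `rank` column is added if missing).
#' @return A ggplot object.
#' @export
plot_mir_ranks <- function(profiles) {
  profiles <- as_tibble(profiles)
  if (!"rank" %in% names(profiles)) {
    profiles <- rank_mir_profiles(profiles)
  }
  if (!"excess" %in% names(profiles)) profiles$excess <- FALSE
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$rank, y = .data$n_mir_outliers)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$excess), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "red"),
      labels = c(`FALSE` = "cohort", `TRUE` = "excess of MIR"),
      name = NULL
    ) +
    ggplot2::facet_wrap(~tissue, scales = "free") +
    ggplot2::labs(
      x = "individuals, ranked by MIR outlier count",
      y = "significant MIR outliers"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_mir_ranks
#' @param object A `mir_analysis`.
#' @param ... Unused.
#' @export
autoplot.mir_analysis <- function(object, ...) {
  plot_mir_ranks(object$profiles)
}

#' Theta distribution at selected introns
#'
#' Cohort-wide view of theta at given introns, useful for inspecting an
#' individual call against the cohort spread.
#'
#' @param theta_tbl Output of [compute_theta()].
#' @param introns Tibble of intron keys (`chrom`, `start`, `end`,
#'   `strand`) to display.
#' @param highlight Optional sample IDs drawn in colour.
#' @return A ggplot object.
#' @export
plot_theta_cohort <- function(theta_tbl, introns, highlight = NULL) {
  key <- intron_key(introns)
  theta_tbl <- filter(theta_tbl, !is.na(.data$theta))
  theta_tbl$intron <- intron_key(theta_tbl)
  sub <- filter(theta_tbl, .data$intron %in% key)
  sub$highlighted <- sub$sample_id %in% (highlight %||% character(0))
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$intron, y = .data$theta)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$highlighted),
                         width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey50", `TRUE` = "red"), guide = "none"
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(theta)) +
    ggplot2::theme_minimal()
}
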