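#' Read a long-format splice-site count table
#'
#' One row per (sample, splice site): `sample_id`, `tissue`, the intron key
#' columns `chrom`/`start`/`end`/`strand`, the site end (`donor` or
#' `acceptor`), the split-read count `k_split` (reads spliced across the
#' site) and the nonsplit spanning-read count `m_nonsplit` (reads reading
#' through the exon-intron boundary, i.e. supporting retention).
#'
#' @param path TSV path with the columns above.
#' @return A tibble of splice-site counts.
#' @export
read_splice_counts <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = "c", tissue = "c", chrom = "c", start = "d", end = "d",
      strand = "c", site_end = "c", k_split = "d", m_nonsplit = "d"
    ),
    progress = FALSE
  )
  validate_splice_counts(x)
}

validate_splice_counts <- function(counts) {
  counts <- as_tibble(counts)
  required <- c("sample_id", "tissue", "chrom", "start", "end", "strand",
                "site_end", "k_split", "m_nonsplit")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols) > 0) {
    abort(paste0("count table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(counts$k_split < 0) || any(counts$m_nonsplit < 0)) {
    abort("read counts must be non-negative")
  }
  if (!all(counts$site_end %in% c("donor", "acceptor"))) {
    abort("site_end must be 'donor' or 'acceptor'")
  }
  counts
}

#' Compute the theta splicing-efficiency metric
#'
#' theta = k / (k + m): the fraction of reads informative at a splice site
#' that support splicing. Low theta indicates partial or full intron
#' retention; the retention fraction is 1 - theta. Sites with coverage
#' k + m below `min_coverage` get a missing theta and are excluded from
#' null fitting and testing downstream (never imputed).
#'
#' @param counts Splice-site count tibble (see [read_splice_counts()]).
#' @param min_coverage Minimum informative reads per (sample, site);
#'   default 10, a floor that prevents theta estimates from 1-2 reads.
#' @return `counts` with `n_total` and `theta` columns added.
#' @export
compute_theta <- function(counts, min_coverage = 10) {
  if (min_coverage < 1) abort("min_coverage must be >= 1")
  counts <- validate_splice_counts(counts)
  counts %>%
    mutate(
      n_total = .data$k_split + .data$m_nonsplit,
      theta = if_else(.data$n_total >= min_coverage,
                      .data$k_split / .data$n_total, NA_real_)
    )
}

#' Collapse site-level test results to intron level
#'
#' Donor and acceptor sites of the same intron each carry a theta test;
#' retention is reported per intron, so per (sample, intron) the site with
#' the smaller q is retained (ties broken by larger absolute delta, then
#' donor). Introns with no testable site for a sample are omitted.
#'
#' @param records Per-(sample, site) tibble carrying `q` and `delta`
#'   columns (from [adjust_fdr()]).
#' @return One row per (sample, intron), invariant to input row order.
#' @export
collapse_to_intron <- function(records) {
  records <- as_tibble(records)
  records %>%
    filter(!is.na(.data$q)) %>%
    arrange(.data$sample_id, .data$chrom, .data$start, .data$end,
            .data$strand, .data$q, dplyr::desc(abs(.data$delta)),
            .data$site_end != "donor") %>%
    distinct(.data$sample_id, .data$chrom, .data$start, .data$end,
             .data$strand, .keep_all = TRUE)
}
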