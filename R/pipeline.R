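#' Run the minor intron retention outlier pipeline
#'
#' Full chain from splice-site counts to per-individual MIR profiles:
#' theta computation, per-site beta-binomial cohort nulls, two-sided
#' p-values, per-sample BH correction, collapse to intron level,
#' significance calling (`q < q_max`, `|delta| >= delta_min`), restriction
#' to minor introns, per-individual MIR/MIG counting and tissue-stratified
#' excess flagging (> `sd_multiplier` SDs above the tissue mean).
#'
#' @param counts Long splice-site count tibble (see
#'   [read_splice_counts()]) or a path to one; a `mir_sim` bundle is also
#'   accepted directly.
#' @param introns Intron registry tibble (see
#'   [read_intron_annotations()]) or a path; ignored when `counts` is a
#'   `mir_sim` (its own registry is used).
#' @param q_max,delta_min Outlier significance thresholds
#'   (defaults 0.05 and 0.3).
#' @param sd_multiplier Excess-of-MIR threshold in cohort SDs (default 2).
#' @param min_coverage Minimum informative reads per observation
#'   (default 10).
#' @param min_fit_samples Minimum covered samples per site null
#'   (default 20).
#' @param direction Count outliers in `"both"` directions (default) or
#'   `"retention"` only.
#' @param fdr_scope `"sample"` (default) or `"cohort"` BH family.
#' @param verbose Log record counts at stage boundaries.
#' @return A `mir_analysis` object: `outliers` (all intron-level records
#'   with flags), `calls` (significant minor-intron calls), `profiles`
#'   (per-sample counts, Z, excess), `stats` (tissue cohort summaries),
#'   `tally` (minor/major/unannotated restriction counts), `params`.
#' @export
run_mir_pipeline <- function(counts, introns = NULL,
                             q_max = 0.05, delta_min = 0.3,
                             sd_multiplier = 2, min_coverage = 10,
                             min_fit_samples = 20,
                             direction = c("both", "retention"),
                             fdr_scope = c("sample", "cohort"),
                             verbose = FALSE) {
  direction <- match.arg(direction)
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(q_max > 0, delta_min > 0, sd_multiplier > 0)
  if (inherits(counts, "mir_sim")) {
    introns <- counts$introns
    counts <- counts$counts
  }
  if (is.character(counts)) counts <- read_splice_counts(counts)
  if (is.character(introns)) introns <- read_intron_annotations(introns)
  if (is.null(introns)) abort("an intron registry is required")
  counts <- validate_splice_counts(counts)

  samples <- distinct(counts, .data$sample_id, .data$tissue)
  tissue_sizes <- count(samples, .data$tissue)
  if (any(tissue_sizes$n < 2)) {
    abort(paste0("tissue stratum '",
                 tissue_sizes$tissue[tissue_sizes$n < 2][1],
                 "' has a single sample; cohort statistics need >= 2"))
  }

  theta_tbl <- compute_theta(counts, min_coverage = min_coverage)
  # under-covered observations carry no information downstream (theta
  # missing, never tested or imputed); dropping them here keeps the
  # stage functions general but the pipeline lean
  theta_tbl <- filter(theta_tbl, !is.na(.data$theta))
  nulls <- fit_site_nulls(theta_tbl, min_fit_samples = min_fit_samples)
  n_testable <- sum(nulls$testable)
  if (n_testable == 0) {
    abort(paste0("zero testable splice sites (", nrow(nulls),
                 " sites observed; min_coverage = ", min_coverage,
                 ", min_fit_samples = ", min_fit_samples, ")"))
  }
  scored <- score_outliers(theta_tbl, nulls)
  scored <- adjust_fdr(scored, scope = fdr_scope)
  intron_level <- collapse_to_intron(scored)
  called <- call_outliers(intron_level, q_max = q_max,
                          delta_min = delta_min)
  called <- annotate_calls(called, introns)
  sig <- filter(called, .data$significant)
  minor_calls <- restrict_to_minor(sig, introns)
  tally <- attr(minor_calls, "mirout_tally")

  profiles <- count_mir_outliers(minor_calls, samples,
                                 direction = direction) %>%
    flag_excess(sd_multiplier = sd_multiplier) %>%
    rank_mir_profiles()
  stats_tbl <- cohort_summary(profiles)

  if (verbose) {
    inform(sprintf(
      "sites tested: %d | significant calls: %d | minor-restricted: %d | excess-flagged: %d",
      n_testable, nrow(sig), nrow(minor_calls), sum(profiles$excess)
    ))
  }

  structure(
    list(
      outliers = called,
      calls = minor_calls,
      profiles = profiles,
      stats = stats_tbl,
      tally = tally,
      n_sites_testable = n_testable,
      params = list(q_max = q_max, delta_min = delta_min,
                    sd_multiplier = sd_multiplier,
                    min_coverage = min_coverage,
                    min_fit_samples = min_fit_samples,
                    direction = direction, fdr_scope = fdr_scope)
    ),
    class = "mir_analysis"
  )
}

#' Run the snRNA variant prioritization pipeline
#'
#' Reads variants (VCF path or tibble), applies the rare-variant filters
#' (AF < `af_max`, region-aware CADD >= `cadd_min`, inside the gene
#' span), and reports a summary-table-style tibble with HGVS n.
#' annotation, structural region and duplex partner per variant.
#'
#' @param variants VCF path or tibble with `chrom`, `pos`, `ref`, `alt`
#'   and optional `af`, `cadd`, `phylop`, `inheritance`.
#' @param model An [snrna_gene_model()] or path to a YAML gene model.
#' @param af_max,cadd_min Filter thresholds (defaults 0.01 and 11.44).
#' @param annotations Optional side table of scores for VCF input
#'   (see [read_snrna_variants()]).
#' @return A `mir_variant_report`: annotated tibble `variants`, the
#'   deduplicated passing set `retained`, and a `summary` of counts
#'   retained/dropped per reason.
#' @export
run_variant_pipeline <- function(variants, model, af_max = 0.01,
                                 cadd_min = 11.44, annotations = NULL) {
  if (is.character(model)) model <- read_gene_model(model)
  if (is.character(variants)) {
    variants <- read_snrna_variants(variants, annotations = annotations)
  }
  variants <- as_tibble(variants)
  if (nrow(variants) == 0) {
    warn("no variant records; empty report")
  }
  ann <- apply_prioritization(variants, model, af_max = af_max,
                              cadd_min = cadd_min)
  retained <- ann %>%
    filter(.data$passed) %>%
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
             .keep_all = TRUE)
  reasons <- unlist(strsplit(ann$fail_reasons[!ann$passed], ","))
  reasons <- reasons[nzchar(reasons)]
  summary <- list(
    n_input = nrow(ann),
    n_passed = sum(ann$passed),
    n_retained_unique = nrow(retained),
    dropped_by_reason = as.list(table(reasons))
  )
  structure(
    list(variants = ann, retained = retained, summary = summary,
         model = model,
         params = list(af_max = af_max, cadd_min = cadd_min)),
    class = "mir_variant_report"
  )
}

#' Write a MIR analysis report bundle
#'
#' Emits `outliers.tsv` (intron-level records with flags),
#' `profiles.tsv` (per-sample MIR profile), `cohort_summary.json`
#' (tissue statistics plus run parameters and a provenance block) and
#' `rank_scatter.tsv` (rank-ordered per-individual counts).
#'
#' @param analysis A `mir_analysis` from [run_mir_pipeline()].
#' @param dir Output directory, created if needed.
#' @return Named vector of file paths, invisibly.
#' @export
write_mir_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "mir_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    outliers = file.path(dir, "outliers.tsv"),
    profiles = file.path(dir, "profiles.tsv"),
    summary = file.path(dir, "cohort_summary.json"),
    scatter = file.path(dir, "rank_scatter.tsv")
  )
  readr::write_tsv(analysis$outliers, paths[["outliers"]],
                   progress = FALSE)
  readr::write_tsv(analysis$profiles, paths[["profiles"]],
                   progress = FALSE)
  jsonlite::write_json(
    list(
      schema_version = "1.0",
      stats = analysis$stats,
      tally = as.list(analysis$tally),
      n_sites_testable = analysis$n_sites_testable,
      params = analysis$params,
      provenance = list(
        package = "mirout",
        package_version = as.character(utils::packageVersion("mirout")),
        r_version = R.version.string,
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    paths[["summary"]],
    auto_unbox = TRUE, digits = NA
  )
  readr::write_tsv(
    select(analysis$profiles, "tissue", "rank", "sample_id",
           "n_mir_outliers", "excess"),
    paths[["scatter"]], progress = FALSE
  )
  invisible(paths)
}

#' @method print mir_analysis
#' @export
print.mir_analysis <- function(x, ...) {
  cat("<mir_analysis>\n")
  cat("  testable splice sites:", x$n_sites_testable, "\n")
  cat("  significant minor-intron calls:", nrow(x$calls),
      sprintf("(major-matched: %d, unannotated: %d)\n",
              x$tally[["major"]], x$tally[["unannotated"]]))
  cat("  excess-of-MIR individuals:", sum(x$profiles$excess), "of",
      nrow(x$profiles), "\n")
  print(x$stats)
  invisible(x)
}

#' @method print mir_variant_report
#' @export
print.mir_variant_report <- function(x, ...) {
  cat("<mir_variant_report> gene", x$model$name, "\n")
  cat("  input records:", x$summary$n_input,
      "| passed:", x$summary$n_passed,
      "| unique retained:", x$summary$n_retained_unique, "\n")
  print(select(x$retained, dplyr::any_of(c(
    "chrom", "pos", "ref", "alt", "hgvs_n", "af", "cadd", "phylop",
    "region_label", "partner_gene", "partner_pos"
  ))))
  invisible(x)
}

#' Tidy a MIR analysis into per-sample rows
#'
#' @param x A `mir_analysis`.
#' @param ... Unused.
#' @return The per-sample profile tibble (`sample_id`, `tissue`,
#'   `n_mir_outliers`, `n_migs`, `z`, `excess`, `rank`).
#' @export
tidy.mir_analysis <- function(x, ...) {
  x$profiles
}

#' One-row-per-tissue summary of a MIR analysis
#'
#' @param x A `mir_analysis`.
#' @param ... Unused.
#' @return The tissue cohort-summary tibble with call tallies attached.
#' @export
glance.mir_analysis <- function(x, ...) {
  x$stats %>%
    mutate(
      n_excess = purrr::map_int(
        .data$tissue,
        ~ sum(x$profiles$excess[x$profiles$tissue == .x])
      )
    )
}

#' Write a variant prioritization report
#'
#' Emits `variants.tsv` (one row per input record: genomic coordinate,
#' HGVS n., AF, CADD, PhyloP, structural region, duplex partner, pass
#' flag and failure reasons) and `submission_summary.tsv`, a
#' submission-friendly per-unique-variant table (gene, HGVS n., genomic
#' coordinate, classification placeholder left to the curator).
#'
#' @param report A `mir_variant_report` from [run_variant_pipeline()].
#' @param dir Output directory, created if needed.
#' @return Named vector of file paths, invisibly.
#' @export
write_variant_report <- function(report, dir) {
  stopifnot(inherits(report, "mir_variant_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    variants = file.path(dir, "variants.tsv"),
    submission = file.path(dir, "submission_summary.tsv")
  )
  readr::write_tsv(report$variants, paths[["variants"]], progress = FALSE)
  submission <- report$retained %>%
    mutate(
      gene = report$model$name,
      coordinate = paste0(.data$chrom, ":", .data$pos, .data$ref, ">",
                          .data$alt)
    ) %>%
    select("gene", "hgvs_n", "coordinate",
           dplyr::any_of(c("af", "cadd", "phylop", "region_label",
                           "inheritance")))
  readr::write_tsv(submission, paths[["submission"]], progress = FALSE)
  invisible(paths)
}
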