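#' Simulation configuration for a synthetic splicing cohort
#'
#' Defines the generative model for a cohort of splice-site count tables:
#' a registry of minor and major introns grouped into genes (each minor
#' intron-containing gene carries 1-3 minor and several major introns),
#' per-intron baseline retention drawn from a Beta distribution, negative
#' binomial site coverage, beta-binomial read noise within sites, tissue
#' expression masks (blood-like tissue expresses most minor introns,
#' fibroblast-like tissue few), and an additive retention shift injected
#' into designated affected samples at a fraction of their expressed
#' minor introns.
#'
#' @param n_samples Cohort size (default 100).
#' @param tissues Tissue label per sample (recycled; default `"blood"`).
#' @param n_minor,n_major Numbers of minor and major introns
#'   (defaults 500 and 2000).
#' @param baseline_mean,baseline_conc Beta distribution of per-intron
#'   baseline retention: mean 0.02 and concentration 30 by default, i.e.
#'   low baseline retention with occasional constitutively retained
#'   introns.
#' @param coverage_mean,coverage_size Negative binomial site coverage
#'   (mean 30 reads, size 5 by default).
#' @param noise_rho Beta-binomial overdispersion of read counts within a
#'   (sample, site) beyond the intron's retention level (default 0.01).
#' @param affected Indices or sample IDs of affected individuals
#'   (default none: a null cohort).
#' @param effect_size Additive retention shift in affected samples
#'   (default 0.4), clamped into `[0, 1]`.
#' @param affected_frac Fraction of an affected sample's expressed
#'   minor introns receiving the shift (default 0.125, i.e. about 50
#'   introns for a blood-like sample with 500 minor introns at 80%
#'   expression).
#' @param inject_class Intron class receiving the shift: `"minor"`
#'   (default) or `"major"` (specificity control).
#' @param expressed_frac Named list of per-tissue expressed fractions,
#'   each a named vector `c(minor =, major =)`. Defaults: blood expresses
#'   80% of minor introns, fibroblast 8% (a 10-fold contrast), both
#'   express 80% of major introns.
#' @param seed Mandatory integer seed; all draws flow from it, with
#'   per-sample substreams derived deterministically so enlarging the
#'   cohort does not reshuffle existing samples.
#' @return A `mir_sim_config` list.
#' @export
mir_sim_config <- function(n_samples = 100,
                           tissues = "blood",
                           n_minor = 500,
                           n_major = 2000,
                           baseline_mean = 0.02,
                           baseline_conc = 30,
                           coverage_mean = 30,
                           coverage_size = 5,
                           noise_rho = 0.01,
                           affected = integer(0),
                           effect_size = 0.4,
                           affected_frac = 0.125,
                           inject_class = c("minor", "major"),
                           expressed_frac = list(
                             blood = c(minor = 0.8, major = 0.8),
                             fibroblast = c(minor = 0.08, major = 0.8)
                           ),
                           seed) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory")
  inject_class <- match.arg(inject_class)
  tissues <- rep_len(as.character(tissues), n_samples)
  if (!all(tissues %in% names(expressed_frac))) {
    abort("every tissue needs an entry in expressed_frac")
  }
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  if (is.numeric(affected)) affected <- sample_ids[affected]
  if (!all(affected %in% sample_ids)) {
    abort("affected samples must be members of the cohort")
  }
  structure(
    list(n_samples = n_samples, tissues = tissues, sample_ids = sample_ids,
         n_minor = n_minor, n_major = n_major,
         baseline_mean = baseline_mean, baseline_conc = baseline_conc,
         coverage_mean = coverage_mean, coverage_size = coverage_size,
         noise_rho = noise_rho, affected = affected,
         effect_size = effect_size, affected_frac = affected_frac,
         inject_class = inject_class, expressed_frac = expressed_frac,
         seed = as.integer(seed)),
    class = "mir_sim_config"
  )
}

#' Default signal-recovery scenario
#'
#' The reference simulation used for power checks: 100 samples of one
#' tissue, one affected individual, 500 minor and 2000 major introns,
#' mean coverage 30 and a +0.4 retention shift at 12.5% of the affected
#' sample's expressed minor introns (about 50 introns in blood).
#'
#' @param seed Integer seed.
#' @param tissue Tissue label for the whole cohort (default `"blood"`).
#' @param ... Overrides passed to [mir_sim_config()].
#' @return A `mir_sim_config`.
#' @export
mir_recovery_config <- function(seed, tissue = "blood", ...) {
  mir_sim_config(n_samples = 100, tissues = tissue, affected = 1,
                 seed = seed, ...)
}

#' Simulate a synthetic splicing cohort
#'
#' Generates splice-site counts, a matching intron registry and a truth
#' table under a [mir_sim_config()]. For each (sample, site): coverage
#' n ~ negative binomial; retention r is the intron baseline plus the
#' injected shift for affected samples (clamped to `[0, 1]` with a
#' warning when clamping occurs); the nonsplit count
#' m ~ beta-binomial(n, r, noise_rho) and k = n - m, so theta = k/(k+m)
#' decreases under injected retention. Unexpressed sites get zero
#' coverage. Deterministic under a fixed seed.
#'
#' @param config A [mir_sim_config()].
#' @return A `mir_sim` list: `counts` (long tibble), `introns`
#'   (registry tibble), `samples` (sample/tissue tibble), `truth`
#'   (affected IDs, injected introns per sample, per-intron baseline
#'   retention), and `config`.
#' @export
simulate_mir_cohort <- function(config) {
  stopifnot(inherits(config, "mir_sim_config"))
  set.seed(config$seed)
  introns <- .sim_intron_registry(config$n_minor, config$n_major)
  n_introns <- nrow(introns)
  baseline <- rbeta(n_introns,
                    config$baseline_mean * config$baseline_conc,
                    (1 - config$baseline_mean) * config$baseline_conc)

  tissue_names <- names(config$expressed_frac)
  masks <- lapply(tissue_names, function(tis) {
    frac <- config$expressed_frac[[tis]]
    stats::runif(n_introns) <
      unname(frac[introns$intron_class])[seq_len(n_introns)]
  })
  names(masks) <- tissue_names

  substream <- sample.int(.Machine$integer.max - 1L, config$n_samples)

  n_sites <- 2L * n_introns
  k_mat <- matrix(0L, nrow = n_sites, ncol = config$n_samples)
  m_mat <- matrix(0L, nrow = n_sites, ncol = config$n_samples)
  injected <- vector("list", config$n_samples)
  clamped_any <- FALSE

  for (s in seq_len(config$n_samples)) {
    set.seed(substream[s])
    tis <- config$tissues[s]
    expressed <- masks[[tis]]
    r <- baseline
    inj <- integer(0)
    if (config$sample_ids[s] %in% config$affected) {
      pool <- which(expressed & introns$intron_class == config$inject_class)
      n_inj <- round(config$affected_frac * length(pool))
      if (n_inj > 0) {
        inj <- sort(sample(pool, n_inj))
        shifted <- r[inj] + config$effect_size
        if (any(shifted > 1)) clamped_any <- TRUE
        r[inj] <- pmin(pmax(shifted, 0), 1)
      }
    }
    injected[[s]] <- inj
    site_r <- rep(r, each = 2L)
    site_expr <- rep(expressed, each = 2L)
    cov <- rnbinom(n_sites, size = config$coverage_size,
                   mu = config$coverage_mean)
    cov[!site_expr] <- 0L
    p_site <- site_r
    if (config$noise_rho > 0) {
      mid <- site_r > 0 & site_r < 1
      rho <- config$noise_rho
      p_site[mid] <- rbeta(sum(mid),
                           site_r[mid] * (1 - rho) / rho,
                           (1 - site_r[mid]) * (1 - rho) / rho)
    }
    m <- rbinom(n_sites, cov, p_site)
    m_mat[, s] <- m
    k_mat[, s] <- cov - m
  }
  if (clamped_any) {
    warn("injected retention exceeded 1 at some introns; clamped to 1")
  }

  counts <- tibble(
    sample_id = rep(config$sample_ids, each = n_sites),
    tissue = rep(config$tissues, each = n_sites),
    chrom = rep(rep(introns$chrom, each = 2L), config$n_samples),
    start = rep(rep(introns$start, each = 2L), config$n_samples),
    end = rep(rep(introns$end, each = 2L), config$n_samples),
    strand = rep(rep(introns$strand, each = 2L), config$n_samples),
    site_end = rep(rep(c("donor", "acceptor"), n_introns),
                   config$n_samples),
    k_split = as.integer(k_mat),
    m_nonsplit = as.integer(m_mat)
  )

  injected_tbl <- dplyr::bind_rows(lapply(seq_len(config$n_samples),
                                          function(s) {
    if (length(injected[[s]]) == 0) return(NULL)
    tibble(sample_id = config$sample_ids[s],
           chrom = introns$chrom[injected[[s]]],
           start = introns$start[injected[[s]]],
           end = introns$end[injected[[s]]],
           strand = introns$strand[injected[[s]]])
  }))
  if (is.null(injected_tbl) || nrow(injected_tbl) == 0) {
    injected_tbl <- tibble(sample_id = character(), chrom = character(),
                           start = numeric(), end = numeric(),
                           strand = character())
  }

  structure(
    list(
      counts = counts,
      introns = introns,
      samples = tibble(sample_id = config$sample_ids,
                       tissue = config$tissues),
      truth = list(
        affected = config$affected,
        injected = injected_tbl,
        baseline = mutate(introns, retention = baseline)
      ),
      config = config
    ),
    class = "mir_sim"
  )
}

# Build a synthetic intron inventory: minor introns grouped into MIGs of
# 1-3 minor introns with 2-6 major introns each; remaining major introns
# grouped into non-MIG genes of 4-8 introns. Coordinates are consecutive
# 0-based half-open intervals on one synthetic chromosome.
.sim_intron_registry <- function(n_minor, n_major) {
  gene_id <- character(0)
  intron_class <- character(0)
  mig_i <- 0L
  left_minor <- n_minor
  left_major <- n_major
  while (left_minor > 0) {
    mig_i <- mig_i + 1L
    n_mi <- min(sample(1:3, 1), left_minor)
    n_ma <- min(sample(2:6, 1), left_major)
    gene <- sprintf("MIG%04d", mig_i)
    gene_id <- c(gene_id, rep(gene, n_mi + n_ma))
    intron_class <- c(intron_class, rep("minor", n_mi), rep("major", n_ma))
    left_minor <- left_minor - n_mi
    left_major <- left_major - n_ma
  }
  g_i <- 0L
  while (left_major > 0) {
    g_i <- g_i + 1L
    n_ma <- min(sample(4:8, 1), left_major)
    gene_id <- c(gene_id, rep(sprintf("G%04d", g_i), n_ma))
    intron_class <- c(intron_class, rep("major", n_ma))
    left_major <- left_major - n_ma
  }
  n <- length(gene_id)
  start <- (seq_len(n) - 1) * 1000
  intron_registry(tibble(
    chrom = "chrS",
    start = start,
    end = start + 500,
    strand = "+",
    gene_id = gene_id,
    intron_class = intron_class,
    subtype = if_else(intron_class == "minor", "AT-AC", "GT-AG")
  ))
}

#' Write a simulated cohort to fixture files
#'
#' Emits `counts.tsv`, `introns.tsv` and `truth.json` readable by
#' [read_splice_counts()], [read_intron_annotations()] and
#' [read_mir_truth()]; a write/load round trip reproduces the simulated
#' tables exactly.
#'
#' @param sim A `mir_sim` from [simulate_mir_cohort()].
#' @param dir Output directory, created if needed.
#' @param force Overwrite into an existing non-empty directory.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_mir_fixture <- function(sim, dir, force = FALSE) {
  stopifnot(inherits(sim, "mir_sim"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    abort(paste0("directory '", dir, "' is not empty; use force = TRUE"))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    introns = file.path(dir, "introns.tsv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_tsv(sim$counts, paths[["counts"]], progress = FALSE)
  write_intron_annotations(sim$introns, paths[["introns"]])
  jsonlite::write_json(
    list(
      affected = sim$truth$affected,
      injected = sim$truth$injected,
      baseline = sim$truth$baseline,
      seed = sim$config$seed
    ),
    paths[["truth"]],
    digits = NA
  )
  invisible(paths)
}

#' Read a simulation truth table
#'
#' @param path Path to a `truth.json` written by [write_mir_fixture()].
#' @return List with `affected` (character), `injected` and `baseline`
#'   tibbles, and the generating `seed`.
#' @export
read_mir_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    affected = as.character(x$affected),
    injected = as_tibble(x$injected),
    baseline = as_tibble(x$baseline),
    seed = x$seed
  )
}
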