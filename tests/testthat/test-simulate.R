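small_config <- function(seed, ...) {
  mir_sim_config(n_samples = 30, n_minor = 40, n_major = 120,
                 seed = seed, ...)
}

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_mir_cohort(small_config(7, affected = 1))
  b <- simulate_mir_cohort(small_config(7, affected = 1))
  expect_identical(a$counts, b$counts)
  expect_identical(as.data.frame(a$introns), as.data.frame(b$introns))
  expect_identical(a$truth$injected, b$truth$injected)
})

test_that("adding samples does not reshuffle existing ones", {
  a <- simulate_mir_cohort(small_config(7))
  big <- simulate_mir_cohort(mir_sim_config(n_samples = 35, n_minor = 40,
                                            n_major = 120, seed = 7))
  first <- dplyr::filter(big$counts, sample_id %in% a$samples$sample_id)
  expect_identical(as.data.frame(first), as.data.frame(a$counts))
})

test_that("a null cohort has an empty truth table", {
  sim <- simulate_mir_cohort(small_config(3))
  expect_equal(length(sim$truth$affected), 0)
  expect_equal(nrow(sim$truth$injected), 0)
})

test_that("zero effect leaves injected introns at baseline retention", {
  sim <- simulate_mir_cohort(small_config(11, affected = 1,
                                          effect_size = 0))
  inj <- sim$truth$injected
  expect_gt(nrow(inj), 0)
  key <- paste(inj$chrom, inj$start)
  cts <- dplyr::filter(sim$counts, sample_id == "S001",
                       paste(chrom, start) %in% key,
                       k_split + m_nonsplit > 0)
  obs_ret <- sum(cts$m_nonsplit) / sum(cts$k_split + cts$m_nonsplit)
  base <- sim$truth$baseline
  exp_ret <- mean(base$retention[paste(base$chrom, base$start) %in% key])
  # binomial-scale Monte-Carlo SE on the pooled retention fraction,
  # inflated for the beta noise across sites
  n_tot <- sum(cts$k_split + cts$m_nonsplit)
  se <- sqrt(exp_ret * (1 - exp_ret) / n_tot) * 3
  expect_lt(abs(obs_ret - exp_ret), 3 * se + 0.02)
})

test_that("injection hits only expressed introns of the chosen class", {
  sim <- simulate_mir_cohort(small_config(13, affected = 2))
  inj <- sim$truth$injected
  reg <- sim$introns
  cls <- reg$intron_class[match(paste(inj$chrom, inj$start),
                                paste(reg$chrom, reg$start))]
  expect_true(all(cls == "minor"))

  simM <- simulate_mir_cohort(small_config(13, affected = 2,
                                           inject_class = "major"))
  clsM <- simM$introns$intron_class[
    match(paste(simM$truth$injected$chrom, simM$truth$injected$start),
          paste(simM$introns$chrom, simM$introns$start))]
  expect_true(all(clsM == "major"))
})

test_that("saturating injected retention warns and clamps", {
  expect_warning(
    simulate_mir_cohort(small_config(17, affected = 1, effect_size = 1)),
    "clamped"
  )
})

test_that("fibroblast-like samples express fewer minor-intron sites", {
  sim <- simulate_mir_cohort(
    mir_sim_config(n_samples = 4, tissues = c("blood", "blood",
                                              "fibroblast", "fibroblast"),
                   n_minor = 200, n_major = 200, seed = 19)
  )
  expressed_minor <- sim$counts |>
    dplyr::left_join(
      dplyr::select(sim$introns, chrom, start, end, strand, intron_class),
      by = c("chrom", "start", "end", "strand")
    ) |>
    dplyr::filter(intron_class == "minor",
                  k_split + m_nonsplit > 0) |>
    dplyr::count(tissue, sample_id)
  blood <- expressed_minor$n[expressed_minor$tissue == "blood"]
  fib <- expressed_minor$n[expressed_minor$tissue == "fibroblast"]
  expect_gt(min(blood), max(fib))
})

test_that("fixture write/load round-trips and truth passes through", {
  sim <- simulate_mir_cohort(small_config(23, affected = 1))
  dir <- withr::local_tempdir()
  out <- file.path(dir, "fx")
  paths <- write_mir_fixture(sim, out)
  counts2 <- read_splice_counts(paths[["counts"]])
  expect_equal(as.data.frame(counts2), as.data.frame(sim$counts))
  reg2 <- read_intron_annotations(paths[["introns"]])
  expect_equal(as.data.frame(reg2), as.data.frame(sim$introns))
  truth <- read_mir_truth(paths[["truth"]])
  expect_equal(truth$affected, sim$truth$affected)
  expect_equal(nrow(truth$injected), nrow(sim$truth$injected))
  expect_error(write_mir_fixture(sim, out), "not empty")
  expect_silent(write_mir_fixture(sim, out, force = TRUE))
})
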