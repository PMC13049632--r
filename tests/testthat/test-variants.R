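test_that("published RNU6ATAC variants convert to their HGVS n. names", {
  g <- rnu6atac_model()
  t1 <- table1_entries()
  conv <- genomic_to_snrna(t1, g)
  expect_equal(conv$hgvs_n, t1$hgvs_expected)
  # boundary anchor: genomic end of a minus-strand gene is n.1
  edge <- genomic_to_snrna(
    tibble::tibble(chrom = "chr9", pos = g$end, ref = "A", alt = "G"), g)
  expect_equal(edge$n_pos, 1)
})

test_that("conversion rejects out-of-span and non-SNV input", {
  g <- rnu6atac_model()
  expect_error(
    genomic_to_snrna(tibble::tibble(chrom = "chr9", pos = g$start - 1,
                                    ref = "A", alt = "G"), g),
    "outside gene"
  )
  expect_error(
    genomic_to_snrna(tibble::tibble(chrom = "chr9", pos = g$start,
                                    ref = "AT", alt = "G"), g),
    "SNV only"
  )
  expect_error(
    genomic_to_snrna(tibble::tibble(chrom = "chr9", pos = g$start,
                                    ref = "A", alt = "A"), g),
    "differ"
  )
})

test_that("coordinate conversion round-trips on both strands", {
  minus <- rnu6atac_model()
  plus <- snrna_gene_model("TEST", "chr1", 1000, 1125, "+")
  for (g in list(minus, plus)) {
    pos <- g$start:g$end
    v <- tibble::tibble(chrom = g$chrom, pos = pos,
                        ref = rep(c("A", "C", "G", "T"),
                                  length.out = length(pos)),
                        alt = rep(c("C", "G", "T", "A"),
                                  length.out = length(pos)))
    conv <- genomic_to_snrna(v, g)
    expect_true(all(conv$n_pos >= 1 & conv$n_pos <= g$length))
    back <- snrna_to_genomic(conv$n_pos, conv$ref_n, conv$alt_n, g)
    expect_equal(back$pos, v$pos)
    expect_equal(back$ref, v$ref)
    expect_equal(back$alt, v$alt)
  }
  # plus strand leaves alleles unchanged; complement is an involution
  v <- tibble::tibble(chrom = "chr1", pos = 1010, ref = "G", alt = "T")
  conv <- genomic_to_snrna(v, plus)
  expect_equal(conv$ref_n, "G")
  expect_equal(conv$alt_n, "T")
})

test_that("structural regions and duplex partners match the gene model", {
  g <- rnu6atac_model()
  t1 <- table1_entries()
  conv <- genomic_to_snrna(t1, g)
  struct <- annotate_structure(conv$n_pos, g)
  expect_equal(struct$region_label, t1$region_expected)

  # the stem II duplex pairs U6atac n.43 with the U4atac n.8 hotspot
  n43 <- annotate_structure(43, g)
  expect_equal(n43$partner_gene, "RNU4ATAC")
  expect_equal(n43$partner_pos, 8)

  # the central stem-loop is not a duplex register
  n64 <- annotate_structure(64, g)
  expect_true(is.na(n64$partner_gene))

  expect_equal(annotate_structure(120, g)$region_label, "unassigned")
})

test_that("prioritization applies AF, CADD and span filters with reasons", {
  g <- rnu6atac_model()
  t1 <- table1_entries()
  ann <- apply_prioritization(t1, g)
  expect_true(all(ann$passed))
  expect_equal(ann$fail_reasons, rep("", 6))

  extra <- tibble::tibble(
    chrom = c("chr9", "chr9", "chr9"),
    pos = c(134164537, 134164537, 134164000),
    ref = "G", alt = "A",
    af = c(0.02, NA, NA),
    cadd = c(21, 10, 21)
  )
  got <- apply_prioritization(extra, g)
  expect_equal(got$passed, c(FALSE, FALSE, FALSE))
  expect_equal(got$fail_reasons, c("af", "cadd", "outside_gene"))
  # every record is passed or carries at least one reason
  both <- apply_prioritization(dplyr::bind_rows(t1, extra), g)
  expect_true(all(both$passed | nchar(both$fail_reasons) > 0))
  # absent AF is treated as zero and retained
  expect_true(apply_prioritization(
    tibble::tibble(chrom = "chr9", pos = 134164529, ref = "A", alt = "C",
                   af = NA, cadd = 18), g)$passed)
})

test_that("VCF reading recovers records and INFO scores", {
  vcf <- system.file("extdata", "rnu6atac_variants.vcf",
                     package = "mirout")
  v <- read_snrna_variants(vcf)
  expect_equal(nrow(v), 6)
  expect_equal(sum(is.na(v$af)), 2)
  expect_equal(range(v$cadd), c(18, 21))
  expect_equal(sort(unique(v$pos)),
               c(134164501, 134164522, 134164529, 134164535, 134164537))
  # side table overrides scores
  side <- tibble::tibble(chrom = "chr9", pos = 134164501, ref = "G",
                         alt = "C", cadd = 25)
  v2 <- read_snrna_variants(vcf, annotations = side)
  expect_equal(v2$cadd[v2$pos == 134164501], 25)
})

test_that("variant pipeline reproduces the cohort prioritization", {
  vcf <- system.file("extdata", "rnu6atac_variants.vcf",
                     package = "mirout")
  rep <- run_variant_pipeline(vcf, rnu6atac_model())
  expect_equal(rep$summary$n_input, 6)
  expect_equal(rep$summary$n_passed, 6)
  expect_equal(rep$summary$n_retained_unique, 5)
  expect_setequal(rep$retained$hgvs_n,
                  c("n.28C>T", "n.36T>G", "n.30C>T", "n.64C>G", "n.43G>A"))

  # a vanishing AF ceiling keeps only the two population-absent variants
  strict <- run_variant_pipeline(vcf, rnu6atac_model(), af_max = 1e-9)
  expect_equal(strict$summary$n_retained_unique, 2)
  expect_setequal(strict$retained$hgvs_n, c("n.36T>G", "n.64C>G"))

  expect_warning(
    empty <- run_variant_pipeline(table1_entries()[0, 1:5],
                                  rnu6atac_model()),
    "empty report"
  )
  expect_equal(nrow(empty$retained), 0)
})

test_that("variant report files mirror the summary table", {
  rep <- run_variant_pipeline(
    system.file("extdata", "rnu6atac_variants.vcf", package = "mirout"),
    rnu6atac_model()
  )
  dir <- withr::local_tempdir()
  paths <- write_variant_report(rep, file.path(dir, "v"))
  full <- readr::read_tsv(paths[["variants"]], show_col_types = FALSE)
  expect_equal(nrow(full), 6)
  expect_true(all(c("hgvs_n", "region_label", "passed", "fail_reasons")
                  %in% names(full)))
  sub <- readr::read_tsv(paths[["submission"]], show_col_types = FALSE)
  expect_equal(nrow(sub), 5)
  expect_equal(unique(sub$gene), "RNU6ATAC")
})
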