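# Shared fixture builders and independent oracles.

# Small intron table: 2 minor + 1 major across two genes.
small_intron_tbl <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100, 900, 50),
    end = c(200, 1000, 150),
    strand = c("+", "+", "-"),
    gene_id = c("MIG1", "MIG1", "GENE2"),
    intron_class = c("minor", "minor", "major")
  )
}

write_intron_tsv <- function(tbl, path = withr::local_tempfile(
                               fileext = ".tsv",
                               .local_envir = parent.frame())) {
  readr::write_tsv(tbl, path, progress = FALSE)
  path
}

# One-site cohort count table with given split/nonsplit counts per sample.
one_site_counts <- function(k, m, tissue = "blood",
                            site_end = "donor") {
  n <- length(k)
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    tissue = tissue,
    chrom = "chr1", start = 0, end = 100, strand = "+",
    site_end = site_end,
    k_split = as.integer(k), m_nonsplit = as.integer(m)
  )
}

# Independent beta-binomial two-sided p-value by full PMF enumeration
# (log-gamma closed form, no recurrence), the brute-force oracle.
bb_pvalue_enum <- function(k, n, mu, rho) {
  pmf <- if (rho == 0) {
    stats::dbinom(0:n, n, mu)
  } else {
    a <- mu * (1 - rho) / rho
    b <- (1 - mu) * (1 - rho) / rho
    exp(lchoose(n, 0:n) + lbeta(0:n + a, n - 0:n + b) - lbeta(a, b))
  }
  min(1, 2 * min(sum(pmf[1:(k + 1)]), sum(pmf[(k + 1):(n + 1)])))
}

# Naive Benjamini-Hochberg step-up, written from the definition.
bh_naive <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Table 1 of genetic findings, frozen from the printed values: six
# genotype entries (individual C1 is homozygous, so one variant twice).
table1_entries <- function() {
  tibble::tibble(
    individual = c("A1", "A1", "B1", "B1", "C1", "C1"),
    chrom = "chr9",
    pos = c(134164537, 134164529, 134164535, 134164501,
            134164522, 134164522),
    ref = c("G", "A", "G", "G", "C", "C"),
    alt = c("A", "C", "A", "C", "T", "T"),
    af = c(0.0000789, NA, 0.00000658, NA, 0.00001313, 0.00001313),
    cadd = c(21, 18, 21, 19, 19, 19),
    phylop = c(9.55, 7.12, 7.62, 3.98, 4.72, 4.72),
    hgvs_expected = c("n.28C>T", "n.36T>G", "n.30C>T", "n.64C>G",
                      "n.43G>A", "n.43G>A"),
    region_expected = c(
      "U6atac/U4atac stem I pairing region",
      "U6atac/U4atac stem II pairing region",
      "stem I/II boundary of the U4atac/U6atac bimolecule",
      "central stem-loop region",
      "U6atac/U4atac stem II pairing region",
      "U6atac/U4atac stem II pairing region"
    )
  )
}

ks_uniform_stat <- function(p) {
  n <- length(p)
  sp <- sort(p)
  max(abs(c(seq_len(n) / n - sp, sp - (seq_len(n) - 1) / n)))
}
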