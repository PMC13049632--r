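Package: mirout
Title: Minor Intron Retention Outlier Analysis for Rare-Disease Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects individuals with a transcriptome-wide excess of minor
    (U12-type) intron retention from cohort RNA-seq splice-site counts.
    Computes the theta splicing-efficiency metric from split and nonsplit
    read counts, fits a per-intron beta-binomial cohort null, calls
    retention outliers with per-sample false discovery rate control and an
    effect-size threshold, restricts calls to minor introns, and flags
    individuals whose outlier count exceeds the tissue cohort mean by more
    than two standard deviations. Also prioritizes rare variants in minor
    spliceosome snRNA genes with an allele-frequency filter and a
    region-aware CADD threshold, converting genomic coordinates to
    strand-aware HGVS n. notation with structural-region and duplex-partner
    annotation. Includes a seeded synthetic cohort simulator with
    tissue-specific expression masks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    vctrs,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
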