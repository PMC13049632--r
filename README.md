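# mirout

Detection of individuals with a transcriptome-wide **excess of minor
intron retention (MIR)** from cohort RNA-seq splice-site counts, plus
prioritization of rare variants in minor spliceosome snRNA genes.

## Why

The minor (U12-type) spliceosome excises fewer than 0.5% of human
introns (~770 introns in ~715 genes). When one of its snRNAs (U11, U12,
U4atac, U6atac) is defective, minor introns are retained
transcriptome-wide — the molecular signature of the minor spliceopathies.
Because minor introns are so rare, global intron-retention metrics bury
this signal; it only becomes visible when splicing outliers are
intersected with a minor-intron annotation. And because spliceosomal
snRNA genes are short non-coding genes absent from exome capture kits,
the matching DNA diagnosis needs genome sequencing plus a
non-coding-aware variant filter.

`mirout` implements both halves of that diagnostic loop for
rare-disease transcriptomics cohorts:

1. **MIR outlier profiling.** At every splice site the splicing
   efficiency is θ = k/(k+m), where k counts split (spliced) reads and m
   counts nonsplit reads spanning the exon–intron boundary; low θ means
   retention. Each observation is tested against a per-site
   beta-binomial cohort null (mean μ, overdispersion ρ, method-of-moments
   fit; leave-one-out so a genuine outlier does not inflate its own
   null). Two-sided p-values are BH-adjusted per individual, and an
   observation is a **θ outlier** when q < 0.05 and |Δθ| = |θ − μ| ≥ 0.3.
   Calls are restricted to introns classified *minor* in the annotation,
   counted per individual, and an individual has an **excess of MIR**
   when their count exceeds their tissue cohort's mean by more than 2
   standard deviations.
2. **snRNA variant prioritization.** Variants in a minor spliceosome
   snRNA gene are kept when gnomAD-style allele frequency is < 1% (absent
   = 0) and the CADD Phred score clears the region-aware non-coding
   threshold of 11.44; retained variants are renamed in strand-aware
   HGVS n. notation and annotated with the structural region and
   U4atac/U6atac duplex pairing partner they disturb.

A seeded synthetic cohort generator (beta-binomial retention noise,
negative binomial coverage, tissue-specific expression masks, injected
retention shifts) makes every stage testable end to end without any
controlled-access data.

## Worked example

Simulate the default recovery scenario (100 blood-like samples, one
affected individual with a +0.4 retention shift at ~50 expressed minor
introns) and run the pipeline:

```r
library(mirout)

sim <- simulate_mir_cohort(mir_recovery_config(seed = 42))
res <- run_mir_pipeline(sim)
res
#> <mir_analysis>
#>   testable splice sites: 3958
#>   significant minor-intron calls: 46 (major-matched: 1, unannotated: 0)
#>   excess-of-MIR individuals: 1 of 100
#> # A tibble: 1 x 7
#>   tissue n_samples  mean    sd median iqr_low iqr_high
#>   <chr>      <int> <dbl> <dbl>  <dbl>   <dbl>    <dbl>
#> 1 blood        100  0.46   4.6      0       0        0
```

The affected sample (`sim$truth$affected`, here `S001`) carries 46
significant MIR outliers in 42 distinct minor intron-containing genes
(Z ≈ 9.9) while the rest of the cohort sits at a median of 0 events
(IQR 0–0) — the characteristic "one dot far above a flat cohort"
profile. `tidy(res)` returns the per-sample profile, `glance(res)` the
tissue summary, and `autoplot(res)` draws the rank-ordered scatter.

Variant prioritization on the bundled U6atac gene model and the bundled
VCF of published RNU6ATAC genotypes:

```r
run_variant_pipeline(
  system.file("extdata", "rnu6atac_variants.vcf", package = "mirout"),
  rnu6atac_model()
)
#> <mir_variant_report> gene RNU6ATAC
#>   input records: 6 | passed: 6 | unique retained: 5
#> # A tibble: 5 x 11
#>   chrom       pos ref   alt   hgvs_n           af  cadd phylop region_label
#> 1 chr9  134164501 G     C     n.64C>G NA             19   3.98 central stem-loo…
#> 2 chr9  134164522 C     T     n.43G>A  0.0000131     19   4.72 U6atac/U4atac st…
#> 3 chr9  134164529 A     C     n.36T>G NA             18   7.12 U6atac/U4atac st…
#> 4 chr9  134164535 G     A     n.30C>T  0.00000658    21   7.62 stem I/II bounda…
#> 5 chr9  134164537 G     A     n.28C>T  0.0000789     21   9.55 U6atac/U4atac st…
```

All six genotype entries clear the AF and CADD filters; five unique
variants remain, each annotated with its snRNA-sense HGVS name and the
structural element it hits (n.43, for instance, pairs with the U4atac
n.8 hotspot in the stem II duplex register).

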