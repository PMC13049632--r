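---
title: "Detecting minor intron retention outliers: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting minor intron retention outliers: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirout)
```

## The problem

Minor (U12-type) introns are a tiny fraction of all human introns, and a
defective minor spliceosome leaves them unexcised transcriptome-wide.
In a rare-disease RNA-seq cohort this produces a distinctive profile:
one individual with hundreds of retention outliers confined to minor
introns, against a cohort background whose median count is zero.
`mirout` formalizes that profile as a pipeline:
counts → θ → outlier tests → minor-intron restriction → per-individual
counts → excess flags, with a parallel track that prioritizes candidate
variants in the snRNA genes that could explain the signal.

## The splicing metric

For a splice site observed in a sample, k split reads support splicing
and m nonsplit reads read through the exon–intron boundary;
θ = k/(k+m) is the splicing efficiency and 1−θ the retention fraction.
θ is computed per site end (donor and acceptor separately) because the
two boundaries of an intron have different read support; results are
collapsed back to intron level (the unit in which retention events are
reported) by keeping, per (sample, intron), the site with the smaller q,
breaking ties by larger |Δθ| and then donor. Observations with fewer
than `min_coverage` informative reads (default 10) are missing: a θ
estimated from one or two reads is noise, and missing values are
excluded from fitting and testing, never imputed. The threshold is a
documented guess exposed as an argument; the upstream studies this
design follows do not state their expression filter.

## The cohort null

Across a cohort the split count at a site is modelled as
K ~ beta-binomial(n, μ, ρ): binomial sampling of reads around a
sample-level splicing efficiency that itself varies with overdispersion
ρ (ρ = 0 reduces to binomial). The fit is method-of-moments: μ is the
coverage-weighted mean of θ, and ρ is the one-way ANOVA
intraclass-correlation estimator (Fleiss) on the binary read outcomes
clustered by sample, floored at 0 whenever the empirical variance does
not exceed binomial variance. μ is clamped to
[ε, 1−ε] with ε = 1/(2·median coverage) so that all-or-nothing sites
(e.g. every read split in every sample) still define a proper null.
Sites with fewer than `min_fit_samples` (default 20) covered samples are
reported as untestable rather than dropped.

Two design points deserve emphasis:

* **No latent covariate correction.** Established splicing-outlier
  frameworks correct the cohort null for latent confounders with an
  autoencoder before testing. This package deliberately uses a
  covariate-free per-site null: the discriminating signal here — a
  count of minor-intron outliers orders of magnitude above a
  near-zero background — does not hinge on covariate correction, and the
  simpler null keeps every stage auditable. This is the principal
  modelling deviation from those frameworks and the main caveat when
  moving to real cohorts with batch structure (see *Limitations*).
* **Leave-one-out scoring.** Each observation is tested against the
  site's null re-fitted without that observation, using closed-form
  downdates of the moment sums (so it costs one vectorized pass, not a
  refit per sample). This matters: a genuine outlier in a 100-sample
  cohort inflates the full-cohort moment estimate of ρ severely enough
  to mask itself (in the default recovery scenario the full fit lifts ρ
  from ~0.01 to 0.1–0.4 at injected sites and the signal disappears;
  the leave-one-out fit recovers ~90% of injected introns). Under the
  null the leave-one-out and full fits agree to within estimator noise.

The two-sided p-value is p = 2·min(P(K ≤ k), P(K ≥ k)) capped at 1,
evaluated by a numerically stable probability-ratio recurrence along the
shorter tail (the other tail follows from
P(K ≤ k) + P(K ≥ k) = 1 + P(K = k)); it matches brute-force PMF
enumeration to well below 1e−9 for n ≤ 100. Doubling the minimum tail is
conservative on a discrete support: p-values are approximately uniform
under the null in the effectively-continuous high-coverage regime
(the test suite checks Kolmogorov–Smirnov distance < 0.05 at coverage
500), and sub-uniform (conservative) at typical coverage of 30 — a
deliberate bias direction for an outlier screen.

## Calling, restriction, counting

Benjamini–Hochberg adjustment is applied per individual across all
tested sites — the correction family matches the per-individual counting
that follows. Whether the upstream analyses corrected per sample or
cohort-wide is unstated; per-sample is the default and `fdr_scope`
switches to the pooled family. A call is significant when q < 0.05 and
|Δθ| ≥ 0.3 (both thresholds exposed); the effect-size condition is
two-sided, with the direction recorded so retention-only counting
(Δθ < 0) stays available via `direction = "retention"`.

Significant calls are intersected with the intron registry by exact
(chrom, start, end, strand) key — calls and annotations derive from the
same intron inventory, and overlap semantics would silently merge
adjacent introns. Calls at unannotated introns are tallied and excluded,
not errors. Per individual the pipeline counts MIR outliers and distinct
minor intron-containing genes (MIGs); the cohort summary per tissue uses
the sample SD (n−1; cohorts of 100–400 make the estimator choice nearly
immaterial but n−1 is conventional) and linear-interpolation quartiles
(R type 7), which reproduces the "IQR: 0–0" presentation on degenerate
near-zero backgrounds. An individual is flagged as having an excess of
MIR when count > mean + 2·SD **within their own tissue** — strata are
never pooled, because MIG expression differs strongly by tissue. The
candidate is included in the mean/SD (no hold-out): the rule is defined
on the cohort as observed; excluding candidates would inflate Z scores
and is left as future configuration. When SD = 0, Z is undefined
(reported missing) and nothing is flagged.

## snRNA variant prioritization

The variant track filters VCF records against an snRNA gene model
(YAML: genomic span, strand, named structural regions in snRNA
coordinates, duplex base-pairing registers). A variant passes when it
lies in the gene span, its allele frequency is below 1% — absent AF is
treated as 0 and retained, since variants missing from population
databases are the most interesting — and its CADD Phred score is at
least 11.44, the region-aware threshold for non-coding RNA genes. CADD,
PhyloP and AF are consumed from INFO fields or a side table, never
computed. Failed records are returned with per-condition reasons; the
filter never discards silently.

Coordinate conversion to HGVS n. notation anchors n.1 at the annotated
gene boundary: on the minus strand n = end − pos + 1 with complemented
alleles, on the plus strand n = pos − start + 1. The conversion is an
involution-validated bijection over the gene span (round-trip tested on
both strands). Only SNVs are handled; indel HGVS grammar (del/ins) in a
126-nt gene is deferred. Structural annotation returns the first
configured region containing the position, and the duplex partner by
antiparallel register arithmetic: the i-th position of the own range
pairs with the i-th position of the reversed partner range. The shipped
U6atac model (chr9:134,164,439–134,164,564, minus strand, 126 nt)
validates all five published RNU6ATAC variant conversions and the
n.43 ↔ U4atac n.8 pairing; region boundaries beyond those anchor points
are editable configuration seeded from secondary-structure models, not
asserted facts — published figures show them only graphically.

## The synthetic cohort generator

The generator emulates the structure that makes MIR excess detectable,
with defaults frozen as the reference study conditions:

| parameter | default | meaning |
|---|---|---|
| cohort | 100 samples | one tissue unless specified |
| introns | 500 minor + 2000 major | MIGs carry 1–3 minor + 2–6 major introns |
| baseline retention | Beta(mean 0.02, conc. 30) | low retention, occasional constitutive tail |
| coverage | NB(mean 30, size 5) | per site and sample |
| read noise | beta-binomial ρ = 0.01 | within (sample, site) |
| expressed minor introns | blood 80%, fibroblast 8% | 10× contrast; major introns 80% in both |
| injection | +0.4 retention at 12.5% of the sample's expressed minor introns | ≈50 introns for blood |

Retention is injected on the nonsplit fraction so θ falls at injected
introns; injection targets only expressed introns, which is what makes
the tissue masks interact with recovery the way blood and fibroblast
cohorts do in practice (≈50 vs ≈5 recoverable events, a factor of ~10).
Every draw flows from one seed, with per-sample substreams derived
deterministically so enlarging a cohort leaves existing samples'
counts byte-identical. The generator writes plain-TSV/JSON fixtures that
round-trip through the package's own readers.

What the simulation does **not** model: read-level artifacts (mapping,
GC, length bias), NMD of retained transcripts, correlated donor/acceptor
noise, batch structure, or relatedness between samples. Passing the
recovery and calibration suites therefore demonstrates the statistical
machinery under its stated assumptions, not performance on real
cohorts — in particular, real data with batch confounding would need the
covariate correction this package deliberately omits.

## Problem sizes and numerical choices

The simulation-based checks run at the reference conditions: 20 null
cohorts (calibration: median of per-cohort maximum MIR count 0, flag
rate < 0.10), 100 recovery replicates (affected sample flagged in
≥ 95), 100 specificity replicates with the shift at major introns only
(flag rate ≤ 5%), and 50 paired blood/fibroblast seeds (count ratio in
[5, 20]). Each 100 × 2,500-intron cohort takes ~2.5 s, so the full
acceptance sweep is a 10–15 minute single-CPU computation.

Numerical notes: p-values are floored at the smallest positive double
(the invariant p > 0 survives underflow); ρ is capped at 0.99; the
moment estimator returns 0 on any non-finite intermediate (degenerate
sites); BH is `stats::p.adjust(method = "BH")`; quartiles are
`stats::quantile(type = 7)`. Intron coordinates are 0-based half-open
(BED convention) internally; gene-model and VCF coordinates are 1-based
inclusive as their formats dictate, with readers converting explicitly.

## Limitations

* The covariate-free null assumes exchangeable samples within tissue;
  strong batch effects will inflate ρ and cost power, or worse, create
  spurious outliers. Use the established latent-correction frameworks
  when batch structure is known to be present.
* Leave-one-out protects against a single (or few) outlying samples per
  site; a cohort where many samples share elevated retention at the same
  intron (e.g. several affected relatives) shifts the null itself.
* ψ5/ψ3 alternative-splicing metrics are out of scope: only θ-type
  (retention) outliers are counted.
* The minor/major intron classification is entirely user-supplied; the
  package ships no copy of any intron database and does no coordinate
  lift-over between genome builds.
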