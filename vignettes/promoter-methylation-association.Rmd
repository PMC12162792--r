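---
title: "Methods: promoter methylation and transcription association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter methylation and transcription association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promethex)
library(dplyr)
```

## The scientific question

CpG methylation in gene promoters is one of several layers of
transcriptional regulation: promoters of active genes tend to be lowly
methylated, and increased promoter methylation is often associated with
repression. Two distinct questions can be asked of joint whole-genome
bisulfite sequencing (WGBS) and RNA-seq data:

1. **Static association** — within one condition, do genes with more
   methylated promoters show lower expression?
2. **Dynamic association** — when a treatment changes methylation at a
   gene's promoter, does that gene's expression change too?

`promethex` implements both, for a two-genotype (growth-hormone
transgenic vs. non-transgenic) by three-time-point (fed, feed-deprived,
re-fed) pooled design with two replicate pools per cell — nine pairwise
comparisons in all — together with a synthetic-data generator so every
stage can be tested without the original sequencing data.

## Data model and containers

Internal coordinates are 0-based and half-open everywhere; 1-based
formats (Bismark coverage, GFF3) are converted at the boundary. CpG
sites are keyed by the plus-strand cytosine position after strand
merging (merging itself happens upstream, in the methylation extractor).
Two light containers hold the counts: `cpg_counts` (sites tibble plus
site-by-pool methylated/unmethylated matrices) and `expression_counts`
(gene-by-pool integers with library sizes and normalization factors).
Everything analytic consumes and returns tibbles.

A site absent from one pool is recorded with zero coverage rather than
`NA`; the coverage filter (at least 10 reads in **every** pool, boundary
inclusive) removes such sites before testing, so the two conventions
give the same analysis set.

## Differential methylation

Per unit (CpG site, promoter window, or whole promoter) and comparison,
the model is a binomial logistic regression over the pools'
(methylated, coverage) observations,

$$\mathrm{logit}(p_{i}) = \beta_0 + \beta_1\,\mathrm{group}_i ,$$

tested by the likelihood-ratio statistic for $\beta_1 = 0$. With group
as the only covariate the maximum-likelihood fits are the
coverage-pooled group proportions, which the implementation uses in
closed form; the test suite checks the identity against per-unit
`glm()` fits to $10^{-6}$.

Pooled biological samples carry extra-binomial variance, so the
statistic is corrected for overdispersion: $\hat\varphi$ is the Pearson
$X^2$ of the full model divided by its residual degrees of freedom,
floored at 1, and the corrected statistic $\mathrm{LRT}/\hat\varphi$ is
referred to $\chi^2_1$. This is the simplest standard scaling
correction; the floor means the correction can only make p-values more
conservative. Complete separation is handled by clipping fitted
proportions so that $|\beta_1| \le 20$ on the logit scale.

Multiple testing uses Benjamini–Hochberg across all tested units of a
comparison (genome-wide, not per chromosome — the more conservative and
simpler choice). Calls use the dual threshold $q < 0.01$ **and**
$|\Delta\text{meth}| \ge 25$ percentage points for single CpGs and whole
promoters, or $p < 0.05$ alone for sub-promoter windows (deliberately
less stringent, to probe threshold sensitivity). "Hyper" always means
higher methylation in the second-named group of a comparison.

Coverage normalization divides each pool by the ratio of its median
coverage to the median of all pools' medians, rounding both counts
half-up (this keeps count semantics and bounds the fraction distortion
by one part in the coverage, which the tests assert).

## Differential expression

The expression side re-implements the standard count pipeline from
first principles: CPM filtering (threshold reached in at least the
smallest group-size number of pools), trimmed-mean-of-M-values (TMM)
normalization (reference = pool whose upper-quartile rate is closest to
the mean, 30%/5% two-sided trims on M and A, inverse-asymptotic-variance
weights, factors rescaled to geometric mean 1, smallest index winning
ties), log2-CPM with a depth-scaled prior count, negative-binomial
dispersion estimation, and a per-gene NB log-linear model with
log-effective-library-size offsets tested by likelihood ratio, with BH
FDR at 0.05.

This is an *approximate* re-implementation, not a bit-compatibility
target: acceptance is statistical (null calibration and parameter
recovery). The dispersion estimator maximizes the Cox–Reid-adjusted NB
profile log-likelihood on a 61-point log-spaced grid over
$[10^{-4}, 10]$ with golden-section refinement, using group-wise ratio
estimates of the means; gene-wise grid maxima are shrunk toward the
common value with a prior weight equivalent to 10 residual degrees of
freedom. The "robust" behaviour of the inspiration is approximated by
this shrinkage alone — no outlier down-weighting. On simulated data the
common dispersion recovers the truth (Poisson data give
$\hat\varphi \le 0.01$; $\varphi = 0.1$ is recovered within
$[0.07, 0.13]$ at 2000 genes), and null per-gene p-values are uniform by
a Kolmogorov–Smirnov check.

## Promoter windows

The promoter is defined as 2000 bp upstream to 200 bp downstream of the
TSS, as the TSS-relative half-open interval $[-2000, +200)$ with the TSS
base itself at relative position 0. Windows of 100, 50, 25 and 12.5 bp
tile this span into exactly 22, 44, 88 and 176 windows; a CpG at
(integer) relative position $r$ belongs to window
$\lfloor (r + 2000)/\text{size} \rfloor$, which is exact even for the
12.5 bp size where boundaries are real-valued — no fractional genomic
coordinate ever materializes. Window counts are the sums over member
CpGs after normalization; per gene and size they add up exactly to the
whole-promoter aggregate (a conservation identity asserted on every
simulated genome). Windows with no CpG are excluded from testing rather
than imputed. CpGs inside two overlapping promoters count for both
genes, and windows are tested per gene per window (several significant
windows of one gene are possible, matching the overlap counting rule
below).

## Association analyses

* **Metaplot** — every CpG is assigned to the gene with the nearest TSS
  (ties broken toward the smaller gene id), kept if within 5000 bp
  before to 1000 bp after it, and averaged (coverage-weighted) in 25 bp
  bins; a 5-bin moving average stands in for heavier model-based
  smoothing. Empty bins are omitted.
* **Static association** — ordinary least squares of per-gene mean
  log2-CPM on promoter methylation percent, over genes with both values;
  the fitted object has `tidy()`, `glance()` and `autoplot()` methods.
  The regression uses all such genes; the observation that mostly
  high/low-methylation genes drive the relationship in real tissue is
  noted but not asserted.
* **Dynamic association** — per window position, OLS of per-gene
  expression log2 fold change on the gene's methylation change in that
  window, recording direction and a significance tier
  ($p<0.05$, $<0.01$, $<0.001$; the tier cutoffs are a convention of
  this package). Windows with fewer than 10 genes or a constant
  regressor are skipped. No multiple-testing correction across windows
  by default (`adjust = TRUE` adds BH).
* **DEG–DMR overlap** — a gene overlaps iff it is a DEG (FDR < 0.05)
  and has at least one significant differential-methylation unit in the
  given mode; positional profiles count every significant window of an
  overlapping gene.
* **Derived ratios** — every percentage or ratio in the summary reports
  is a pure function of stored integer tables, with fixed rounding rules
  (transcript-universe percentages to 2 decimals, DEG/window-DMR overlap
  shares to 1, DMR overlap and call-composition percentages to the
  nearest integer, direction ratios to 1 decimal). Feeding the shipped
  published count tables through `derived_ratios()` reproduces the
  published derived values exactly; the test suite asserts all of them.

## The synthetic-data generator

`simulate_experiment()` draws a joint WGBS + RNA-seq dataset with the
structure the analysis assumes:

* One synthetic chromosome; TSSs evenly spaced (default 12 kb) with
  random strands, far enough apart that metaplot spans never overlap
  (an error otherwise). CpGs have exponential spacing (mean 30 bp)
  across each gene's −5000..+1000 span, plus a strictly intergenic
  sparse background (mean 1 kb).
* The mean methylation profile is a plateau (default 0.80) with a
  Gaussian dip to a trough (default 0.15) centred 200 bp downstream of
  the TSS, width 600 bp. These defaults put the profile at ~70%
  methylation 1 kb upstream and reproduce the observed trough location
  and depth. Each gene draws its own plateau and trough uniformly
  (±0.08), which keeps the population means exact, keeps site means
  strictly inside the unit interval (no boundary clipping artifacts),
  and gives genes the between-gene promoter-methylation spread the
  static association needs.
* Counts: coverage is Poisson (default mean 15, matching 12–20×
  sequencing); the methylated fraction is beta-distributed around the
  site mean with overdispersion $\rho$ (default 0.02 — pooled
  individuals imply extra-binomial variance, giving the correction
  something to correct); methylated reads are binomial. An optional
  per-pool noise inflation knob emulates unequal pooled sample sizes
  (default off).
* Treatment effects: a `dm_fraction` of genes has one promoter window
  (default 100 bp, random position or fixed via `dm_window_rel`)
  shifted by ±30 percentage points in all feed-deprivation (Day28)
  pools, reverting after re-feeding. An independent `de_fraction` of
  uncoupled genes receives a ±2 log2 expression shift in the same
  pools. Truth tables list exactly the shifted genes.
* Coupling: expression of a `coupling_fraction` of genes follows
  `log2 mean = baseline + coupling_slope × regulatory methylation %`.
  The regulatory element's baseline level is the gene's true
  promoter-mean methylation (so the static inverse relation holds
  genome-wide), and a differential window shift transmits to it in
  full — a focal-element model chosen because averaging a 12.5–100 bp
  shift over a 2200 bp promoter would dilute the dynamic signal to
  less than one percentage point, leaving nothing for the window-wise
  regressions to detect. The coupling term is centred on the population
  mean methylation so coupled genes are not systematically offset in
  baseline expression (a pure reparameterization of the per-gene
  baseline; all fold changes are unchanged).
* Defaults chosen once where no study value exists:
  `coupling_fraction = 0.5` and `coupling_slope = -0.08` log2 per
  percentage point (a strong, global static relation, as observed in
  liver tissue), `dm_fraction = de_fraction = 0.05`, baseline log2
  expression N(5, 1.5²), library sizes ~3M ± 30%.

All draws sit behind a single integer seed (`withr::with_seed`, with
fixed offsets per stage), so a configuration reproduces byte-identical
data — and `run_pipeline()` reproduces byte-identical TSVs.

**What the generator does and does not emulate.** It reproduces the
profile shape, coverage, pooled-replicate overdispersion, the inverse
methylation–expression relation and window-local differential
methylation. It does not model CpG islands, non-CpG contexts, gene
bodies or enhancers, chromosome structure, or the full between-gene
methylation heterogeneity of real tissue (real promoters span 0–100%
methylation; the generator's spread is deliberately kept inside the
well-calibrated range of the binomial likelihood-ratio test). Passing
property suites therefore demonstrates correctness of the machinery
under the stated model, not performance on any particular real dataset.

## Numerical choices

* Rounding of normalized counts: half-up on both counts independently.
* Ties in TMM reference selection: smallest pool index.
* Nearest-TSS ties in the metaplot: smaller gene id.
* Separation guard in the DM test: fitted proportions clipped at
  $|\mathrm{logit}| \le 20$.
* Dispersion grid: 61 log-spaced points in $[10^{-4}, 10]$ plus
  golden-section refinement; dispersion floor $10^{-8}$ when inverting
  to a GLM `theta`.
* Null-calibration suites run at 60× coverage, the asymptotic regime of
  the $\chi^2$ reference. At the study's 15× the likelihood-ratio test
  is intrinsically ~1 percentage point liberal at nominal 0.05 — a
  small-sample property of the chi-square approximation itself (the
  same at any faithful implementation), not an implementation artifact;
  the overdispersion-corrected p-values are conservative there.
* Test-suite problem sizes: 60-gene experiments for structural checks,
  400–1000 genes for recovery suites, the full 2000-gene default for
  the association and metaplot checks — sizes at which every asserted
  property has comfortable Monte-Carlo margin.

## Annotation units

TSS assignment works at whatever unit the annotation rows carry: a
transcript-level BED/GFF gives transcript-level promoters, a gene-level
one gene-level promoters (records deduplicated by id, first kept). The
generator and the worked examples use one record per gene.

## Known limitations

* The DM test supports exactly two groups and no covariates; no
  smoothing-based DMR calling across neighbouring CpGs.
* The DE module fits a two-group contrast only — no general design
  matrices, no quasi-likelihood F-tests.
* Derived ratios reproduce printed arithmetic exactly only when given
  the same integer tables and rounding rules.
* Per-CpG calling at 15× coverage with two pools per group has very
  little power at the stringent q < 0.01 and 25-point thresholds; the
  window-level aggregation exists precisely because single-CpG counts
  carry too little information at this depth.
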