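---
title: "Methods: amniotic fluid proteomics of term labor and plasma transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amniotic fluid proteomics of term labor and plasma transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laborproteome)
```

## The scientific problem

Parturition involves myometrial contractility, cervical ripening, and
decidual/membrane activation, and these processes project a pro-inflammatory
protein milieu into the amniotic cavity. This package implements a complete
analysis chain for aptamer-based proteomic profiles of that process: it
quantifies how the amniotic fluid (AF) proteome differs between women at
term in labor (TIL) and at term not in labor (TNL), interprets the changes
through gene-set enrichment and placental single-cell signatures, and asks
whether a signature defined in AF still discriminates labor status when
measured in maternal plasma — the cross-compartment transfer that would make
a blood test for true-vs-false labor plausible.

The measurement model throughout is an analytes × samples matrix of
relative fluorescence units (RFU) from a targeted aptamer panel
(one analyte ≈ one protein), analyzed on the log2 scale.

## Differential abundance

For each analyte the two-group comparison uses the classical pooled
statistics: `log2fc` is the difference of group means on the log2 scale
(equivalently the log2 ratio of geometric means), `s2` the pooled residual
variance on `d_g = n1 + n2 - 2` degrees of freedom. Small cohorts
(11 vs 24 here) estimate per-analyte variances poorly, so variances are
moderated by an empirical-Bayes hierarchical model in which true variances
follow a scaled inverse-chi-square prior with `d0` degrees of freedom and
scale `s0^2`. The hyperparameters are fit by method of moments on
`e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)`, solving
`trigamma(d0/2) = var(e) - trigamma(d_g/2)` with a Newton iteration and
setting `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the
moment equation has no positive solution (`var(e)` no larger than the
sampling noise), the prior is taken as infinitely concentrated: `d0 = Inf`
and `s0^2` is the arithmetic mean of the sample variances, which makes the
estimator exact in the identical-variances limit. The moderated statistic
divides `log2fc` by the shrunken standard error and is referred to a
t-distribution with `d0 + d_g` degrees of freedom (Gaussian at
`d0 = Inf`); setting `d0 = 0` disables moderation and reproduces the
ordinary pooled t-test exactly, a limit the tests exercise.

Significance is the joint call used throughout obstetric proteomics here:
Benjamini–Hochberg q < 0.1 (strict inequality) *and* fold change ≥ 1.25,
two-sided on the ratio scale (≥ 1.25 or ≤ 1/1.25). The two-group design is
deliberate — no covariate adjustment, because gestational age at sampling
is matched between groups and shows no association with the principal
components; a gestational-age-adjusted model is out of scope.

## Normalization, concordance, and the PCA meta-proteome

`median_normalize()` is a deliberate stand-in for the vendor's
standardization chain (hybridization control, median signal normalization,
interplate calibration): each sample is rescaled so all sample medians
equal the grand median. It is idempotent and commutes with the log2
transform as a per-sample shift. Cross-platform agreement with
immunoassays is summarized by tie-corrected Spearman correlation with an
exact permutation p below n = 10 (no ties) and the t-approximation above —
the validation subsets this targets have n = 19–30, where the
approximation is standard.

PCA runs on analyte-centered log2 data without variance scaling. Whether
to scale is genuinely open for RFU panels (dynamic range varies by orders
of magnitude across analytes); centering-only is the common default and a
`scale.` flag exposes the alternative. Variance fractions come from the
eigenvalues and sum to one over the returned components. Component–group
association uses Welch's t-test; component–covariate association uses
Pearson correlation.

## Preranked GSEA

The ranking metric is the signed moderated t (the analysis that precedes
it produces exactly this quantity; no separate metric is introduced), with
multiple analytes per gene collapsed to the one with max |t| and ties
broken by gene symbol for reproducibility. The enrichment score is the
classic weighted running sum (hit weight `|t|^p` with `p = 1`, miss
penalty `1/(N - n_set)`), the signed extremum of the walk; the leading
edge is the member genes at or before (after, for negative ES) the
extremum. The null is gene-set permutation — member sets of the same size
resampled uniformly — because the input is a preranked list; a phenotype-
permutation null would need the sample-level data and is not what this
stage consumes. p-values and the FDR are sign-stratified as in standard
GSEA practice: NES is ES over the mean |null ES| of matching sign, and q
is the ratio of null-to-observed NES exceedance fractions, capped at 1 and
monotonized from the most extreme NES inward. Sets with fewer than 5
measured members are skipped; q < 0.25 is reported as significant. An
exhaustive enumeration mode (`choose(N, k)` subsets) makes the permutation
p exact on small problems and anchors the sampled mode in tests.

## Cell-type signatures and the labor signature

Signature gene lists are ordered by preferential expression (most
cell-type-specific first), an ordering taken as given from upstream
single-cell work. Scoring walks that order, keeps genes with a measured
analyte (one analyte per gene, highest mean abundance on ties) up to 20,
and requires at least 5; each analyte is standardized against the TNL
reference group (mean 0, SD 1 in the reference by construction) and the
per-sample mean Z is the signature score. Groups are compared by Wilcoxon
rank-sum — exact when the smaller group has ≤ 12 samples and there are no
ties, normal approximation with continuity and tie correction otherwise
(11-vs-24 sits at this boundary; the cutoff is exposed) — with BH across
all tested cell types as one family, q < 0.1.

The AF labor signature is the top 20 significant-up proteins by log2 fold
change (ties by smaller q, then analyte id). Only the increased direction
is pursued; the decreased proteins do not transfer as a discriminating
aggregate. Mapping into plasma is by gene symbol, order-preserving.

## Plasma classification

The aggregated-Z score in plasma uses only the feature list from AF — a
compartment firewall the tests audit: no AF sample values enter any plasma
computation. Discrimination is summarized by the Mann–Whitney AUC (ties
count one half) with a DeLong placement-variance 95% CI.

The LOOCV random forest protocol holds out one sample, fits a probability
forest on the rest over all candidates (AF significant-up proteins present
on the plasma panel), ranks features by impurity importance
(permutation importance available by flag), refits on the top 10, and
scores the held-out sample; repeating for every sample yields out-of-fold
scores whose AUC is reported with both a DeLong CI and a stratified
bootstrap CI (2000 resamples) — out-of-fold scores are not independent, so
both are shown. Forest size defaults to 500 trees; the number is a
declared default, not an inferred one. Per-fold RNG seeds derive from the
global seed and the held-out sample id, which makes the out-of-fold scores
invariant to sample order, and training rows are put in canonical
(sorted-id) order inside each fold for the same reason.

## The synthetic-data generator

The generator exists so that every stage is testable against known truth
without any external download. Its defaults are the study conditions the
analysis targets: 1310 AF analytes × (11 TNL + 24 TIL), 1125 plasma
analytes × (21 TNL + 59 TIL), 19% of AF analytes differential with 40% of
those increased, |log2FC| uniform on [0.33, 2] (fold changes 1.25–4),
baseline log2 means uniform on [6, 14], per-analyte variances from a
scaled inverse-chi-square with d0 = 4 and s0² = 0.05 (so the eBayes
estimator has a correctly specified target and its recovery can be
tested), 75% panel overlap (placing ~15 of a 20-protein signature on the
plasma panel), and plasma effects attenuated to half the AF effect.
Cross-platform pairs use a Gaussian copula (Pearson `2*sin(pi*rho/6)`
reproduces a target population Spearman rho exactly under monotone maps).
No effect-size distribution is reported for the real cohort's hits, so the
fold-change range is a configurable placeholder spanning the calling
threshold to 4-fold.

What the generator does *not* emulate: plate/batch structure, dilution
bins, aptamer cross-reactivity, heavy-tailed noise, or correlated analyte
blocks. Passing tests therefore demonstrate statistical correctness of the
machinery under a clean hierarchical log-normal model, not robustness to
platform artifacts. Two practical consequences are documented here
deliberately. First, because the generator plants no sample-level scale
effects, median normalization is unnecessary on synthetic data — and on a
cohort whose planted effects are asymmetric (more down than up) it would
inject a small compensating shift into every null analyte; the synthetic
benchmarks therefore log2-transform directly, while the pipeline applies
the normalization as real RFU exports require. Second, the planted effects
are strong relative to the noise floor, so plasma discrimination on
defaults is near-ceiling (AUC ≈ 1); the published real-data regime
(AUC 0.76 aggregated, 0.9 LOOCV) sits well below it, and the package's
classification checks are therefore calibration (permuted labels) and
recovery (planted features) properties, not AUC point reproduction.

## Numerical choices and degenerate inputs

Tables are UTF-8, tab-delimited, `.` decimal, written at 17 significant
digits so read–write is the identity and write–read–write is
byte-identical; non-raw scales travel in a `# scale:` sidecar line. Raw
RFU values must be strictly positive; zero/negative values, duplicate
analyte or sample ids, unannotated samples, constant vectors fed to
correlations, reference groups with zero SD (analyte excluded with a
warning), and gene sets with no measured members all raise located errors
rather than propagating silently. Zero sample variances are floored at
1e-5 of the median with a warning before the hyperparameter fit. The
trigamma inverse uses a damped Newton iteration with closed-form guards at
both extremes. BH adjustment delegates to `stats::p.adjust(method =
"BH")` behind the package's interface and is tested against a literal
brute-force step-up.

## Problem sizes used by the test suite

Oracle-equivalence checks run on hand-sized fixtures (5-analyte moderated
t, 6–8-gene enrichment walks, 1000 random BH vectors). Stochastic checks
use 20 replicates at the default cohort sizes for differential power and
FDR, 20 seeds at m = 5000 for hyperparameter recovery, 50 replicates for
signature null calibration, and 20 replicates for classifier calibration
and recovery; classifier calibration uses a reduced cohort (40 samples, 40
candidates, 300 trees), a size chosen to make the Monte-Carlo loop
proportionate to what it demonstrates. The acceptance script recomputes
the headline quantities at the full default sizes in a single pass.

## Known limitations

The package analyzes one two-group contrast; multi-factor designs, array
weights, and robust/trended variants of the variance prior are out of
scope. The GSEA stage reproduces the method, not any specific gene-set
database release, so term counts from published runs are not comparable
targets. Signature gene rankings are consumed, not derived — deriving them
from single-cell RNA-seq is upstream work. Real supplementary data tables
are not redistributed with the package; `reproduce_af_analysis()` runs the
full published protocol on such tables once the user supplies them.
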