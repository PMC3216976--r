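---
title: "Methods: promoter methylation drift across placental gestation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter methylation drift across placental gestation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestmeth)
```

## The analysis

The human placenta remodels its gene-regulatory landscape over
gestation. On promoter methylation arrays this shows up in two distinct
signals: a *programmed* component — probes whose mean beta-value rises
steadily from first to third trimester — and a *stochastic/environmental*
component — probes whose between-individual variance inflates at term
without any shift in the group mean. `gestmeth` implements the full
analysis that separates and quantifies the two, from raw two-channel
signal pairs to the final clustering report, and ships a synthetic
cohort generator so every stage is verifiable by recovery of planted
ground truth.

A beta-value is the methylated fraction at a CpG probe,

$$\beta = \frac{\max(B, 0)}{\max(A, 0) + \max(B, 0)},$$

with $B$ the methylated-allele and $A$ the unmethylated-allele
intensity; a zero denominator yields a missing value. All downstream
statistics are pairwise-complete: missing cells are excluded from every
mean, variance and correlation rather than imputed (imputation is used
in exactly one place, probe-mean imputation for the clustering distance
matrix, and never feeds back into any analysis table).

## Preprocessing contracts

**Detection filtering.** A cell with detection p ≥ 0.05 is a failed
measurement. The default policy removes a probe that fails in *any*
sample (`drop_any`), because the analyses downstream compare group
summaries over a single shared probe universe; cell-level masking and a
fractional policy are available for cohorts where probe-level exclusion
is too aggressive.

**Normalization.** `normalize_ssn()` applies, per sample and channel,
the order-preserving affine map that sends the channel's 5th percentile
(a background proxy) to the reference channel's 5th percentile and the
channel mean to the reference mean. We deliberately specify the
*contract* — affine, order-preserving, channel means equalized — rather
than any particular implementation's internals: these are the three
properties every downstream stage relies on, and they make the
transformation testable exactly (a sample identical to the reference is
returned unchanged; a channel that is exactly twice the reference maps
onto it; post-normalization channel means agree to 1e-9).

**Batch correction.** Offsets are estimated on the logit scale (betas
clipped to $[10^{-6}, 1-10^{-6}]$; the bound is far below data
resolution and only guards the transform). Per probe, gestational-group
means are removed first and batch offsets are the batch means of the
residuals; this cannot erase a trimester contrast when batches are
balanced across groups, and the function refuses to run when batch is
perfectly confounded with group, since any correction would then
subtract the biology itself.

## The two signals

**Differential methylation.** For each group pair, per-probe
$\Delta\beta$ is the later-minus-earlier difference of group means, a
two-sided pooled-variance t-test supplies the p-value, and
Benjamini–Hochberg step-up controls the FDR. A probe is called at
$|\Delta\beta| \ge 0.2$ (the inclusive `>=` convention) with adjusted
p < 0.05; the laxer $\ge 0.1$ tier is reported alongside. The pooled
test was chosen because group sizes are small and similar and the
beta noise within a group is homoscedastic on this scale; Welch is
available by flag, and moderated (empirical-Bayes) tests are out of
scope by design. Two auxiliary screens reuse the same machinery: the
*fluctuating-pattern* screen flags probes similar in first and third
trimester but deviating in second, and the *transition* comparison
contrasts week-8 against week-12 samples within the first trimester.

**Variability.** Per trimester, each probe's unbiased sample variance
$s^2$ (divisor $n-1$; with group sizes of 10–18 the divisor is
material) is classified as low ($s^2 < 0.009$), intermediate, or highly
variable ($s^2 > 0.02$). Counts of highly variable probes are compared
between trimesters by a Pearson chi-square on the 2×2 table *without*
continuity correction — with the published counts (352 vs 106 highly
variable of 26,162 probes) this statistic reproduces the printed value
133.3 exactly at one decimal, whereas the corrected statistic does not.
The first-vs-third quadrant partition (A = variable in both, B = first
only, C = third only) and the three-trimester Venn partition satisfy
exact bookkeeping identities (A+B equals the first-trimester high
count, and so on) that the tests assert.

**Context and expression.** CGI enrichment of a probe subset is a
one-degree-of-freedom goodness-of-fit chi-square of its observed
CGI/non-CGI split against the analysable-universe background
proportions (a subset-vs-complement 2×2 test is available by flag);
expected cells below 5 flag the result as low-count. TSS-distance
association uses Spearman rank correlation with a seeded permutation
p-value (default 10,000 permutations) because no parametric form is
assumed. Expression integration quartiles *probes* (not genes) by
group-mean beta with stable probe-id tie-breaking, collapses duplicate
expression entries per gene by the median, and calls a gene concordant
when methylation rises by ≥ 0.2 into third trimester while
log-expression is ≥ 1 (2-fold) higher in first trimester, or the exact
mirror. The sign convention follows the integration figure it feeds:
positive $\Delta\beta$ = higher methylation at term, positive logFC =
higher expression in first trimester.

**Validation cleaning.** EpiTYPER-style tables are cleaned by three
rules applied strictly in order, each on the table the previous rule
left: (1) drop samples failing 100% of CpG units; (2) drop units
failing in more than 40% of the remaining samples; (3) drop samples
failing more than 70% of the remaining units. Both percentage bounds
are strict, and rule 2's denominator is the samples surviving rule 1
(the ordering is the point: the tests construct a table where reversing
rules 2 and 3 removes a sample the specified order retains).
Cross-platform agreement is the squared Pearson correlation over
matched (unit, sample) points.

**Clustering.** Samples are clustered on Euclidean distances over all
analysable probes. The default linkage is Ward (`ward.D2`): the
variance-inflated probes at term widen the third-trimester cluster's
*diameter* without giving its samples any shared direction, and
diameter-based criteria (complete linkage) will therefore bridge the
first/second gap before the third group unifies — a failure mode we
verified analytically and empirically. Ward's centroid-based objective
is insensitive to it. Purity is the adjusted Rand index between the
k = 3 tree cut and the trimester labels.

## The synthetic cohort generator

`generate_dataset()` draws a cohort with the statistical structure the
analysis assumes, with every choice exposed in `simulation_config()`:

* **Design**: 18/10/14 samples in first/second/third trimester
  (weeks 8–12, 17–24, 34–41), two processing batches balanced within
  every group.
* **Beta mixture**: baseline probe means fall in three bands —
  63% below 0.2, 24% intermediate, 13% above 0.6 — and 76% of probes
  are CGI-annotated; 4% of probes sit on X/Y and exist only to exercise
  the sex-chromosome filter.
* **Noise**: per-sample betas are Beta-distributed around the probe's
  group mean with precision 100 (SD ≈ 0.05 at intermediate means — a
  realistic inter-individual spread for promoter probes, and one that
  leaves ~98% of null probes below the $s^2 = 0.009$ low-variation
  cut). The Beta family respects the [0,1] support and naturally makes
  intermediate-methylation probes the most variable, which is exactly
  where real variability concentrates.
* **Progressive plants**: 500 intermediate-band probes (80% non-CGI)
  gain 0.15 in mean beta per trimester step, i.e. 0.3 from first to
  third. The step size is chosen so the planted first-to-third gain
  clears the $\Delta\beta \ge 0.2$ calling threshold with high power at
  these group sizes: an effect planted *exactly at* a threshold is
  recovered only ~50% of the time by an unbiased estimator, which would
  make recovery rates meaningless as a correctness check.
* **Variance plants**: 300 intermediate-band probes (90% CGI) receive a
  symmetric two-point dispersal of their third-trimester per-sample
  means — half the samples shifted up by $\delta$, half down, with
  $\delta^2$ plus the base noise variance equal to the target
  $s^2 = 0.03$ (and an $(n-1)/n$ correction so the expectation is
  exact). Dispersing means symmetrically keeps the group mean at its
  baseline, so planted variability is demonstrably *not* a by-product
  of mean change; and a two-point dispersal concentrates the realized
  $s^2$ tightly around the target, where an equal-variance unimodal
  widening would leave recovery at the $s^2 > 0.02$ cut stuck near 82%
  power at $n = 14$ purely from the sampling spread of $s^2$.
* **Instrument layer**: detection failures at rate 3e-4 per cell (the
  scale implied by losing ~1% of probes across 42 samples under
  probe-level exclusion), logit-scale batch offsets of total spread
  0.05, and signal pairs back-computed as $(A, B) = (S(1-\beta),
  S\beta)$ with log-normal total intensity $S$, which makes the beta
  formula an exact inverse of the generator (tested to 1e-12).
* **Expression**: per trimester, gene-level log-expression is
  `intercept + slope × gene beta + noise` with slope −2 — methylation
  represses — so quartile medians must decrease when the machinery is
  correct.

What the generator does *not* emulate: probe-type chemistry (the 27K
design is single-type), IDAT-level artifacts, spatial/positional
effects, imprinting or allele-specific methylation, correlated probe
blocks within promoters, and cell-composition shifts (the
cytotrophoblast question is addressed only through the correlation
operation, applied to an external profile when one is supplied).
Passing recovery tests therefore demonstrates the pipeline's
statistical machinery is correct under a faithful noise model — not
that real placental data meet these assumptions.

## Numerical and boundary conventions

* Beta-band boundaries 0.2 and 0.6 belong to the intermediate band;
  the convention is configurable.
* The differential threshold uses `>=` (the operational table-header
  reading), and the significance default is adjusted p < 0.05.
* The low-variation cut is 0.009 by default, with 0.01 also in
  circulation; both are exposed.
* Zero-variance degenerate probes: equal means give t = 0, p = 1;
  unequal means give the smallest representable positive p rather than
  an exact zero.
* BH adjustment delegates to `stats::p.adjust(method = "BH")` with NAs
  excluded from the test count and propagated; a brute-force step-up
  oracle in the test suite verifies equivalence over a dense grid of
  short p-vectors.
* Quartile ties break by probe id, so repeated runs assign identical
  quartiles.
* The permutation seed for TSS association, the simulation seed, and
  the pipeline seed are all explicit arguments; a fixed seed gives
  byte-identical outputs end to end.

## Problem sizes

The test suite exercises the full study design — a 20,000-probe cohort
with the 18/10/14 sample layout and default plants — once, in the
end-to-end recovery tests, and uses cohorts of 800–8,000 probes for
module-level properties; null-calibration loops run ten 2,000–3,000
probe cohorts. `scripts/acceptance.R` regenerates the 20,000-probe
cohort from its `--seed` argument and recomputes every reported
quantity from scratch in a few seconds on one CPU.

## Known limitations

* The analysis is probe-level throughout; no region-level (multi-probe)
  differential calling, variance-component modelling, or mQTL
  attribution of variance.
* Expression is consumed as already-normalized gene-level tables;
  array-native expression preprocessing belongs upstream.
* The pooled t-test's p-values are approximate for beta-distributed
  data at these sample sizes (the null-calibration test bounds the
  practical impact); rank-based alternatives were not required by any
  downstream consumer.
* Pathway/network enrichment of the called gene sets is intentionally
  absent (the upstream tooling is proprietary); the probe sets and
  gene symbols are emitted for external tools.
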