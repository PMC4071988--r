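---
title: "Genotype-level case-control meta-analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-level case-control meta-analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmeta)
```

## The model

Each study contributes genotype counts for a biallelic SNP — (T1T1,
T1T2, T2T2) in cases and in controls, with T1 the common and T2 the
variant allele. The package never relabels alleles by frequency: the
column order of the input is the contract, because silent relabeling is
a classic source of sign errors in association meta-analyses.

Four contrasts collapse the 3×2 genotype table into 2×2 tables:
homozygote (T2T2 vs T1T1), heterozygote (T1T2 vs T1T1), dominant
(T1T2+T2T2 vs T1T1) and recessive (T2T2 vs T1T1+T1T2). Each yields a
per-study odds ratio with the Woolf standard error on the log scale, a
95% Wald interval (critical value `qnorm(0.975)` = 1.959964, not the
rounded 1.96 — at 2-decimal table precision the difference is invisible,
but tests compare at much tighter tolerances) and a two-sided normal
p-value. Per-allele and additive-trend analyses are deliberately out of
scope: the workflow this package implements analyzes exactly the four
genotype contrasts.

```{r}
auranen <- load_fixture("rs1799794")$studies[[1]]
odds_ratio(build_contrast(auranen, "recessive"))
```

## Pooling and the heterogeneity gate

Cochran's Q is the inverse-variance weighted sum of squared deviations
of the study log ORs about the IV fixed-effects pooled estimate,
referred to chi-square with k−1 df; I² = max(0, (Q−df)/Q) and the
DerSimonian–Laird moment estimator gives τ². Q is always computed about
the IV estimate even when Mantel–Haenszel pooling is selected: the two
pooled estimates are indistinguishable on homogeneous data, and fixing
the convention makes every number in the package reproducible against an
explicit formula.

The model choice mirrors standard practice: random effects iff the Q
p-value is strictly below `heterogeneity_alpha` (default 0.05; 0.10 is
available via `meta_config()` since many meta-analyses prefer it),
otherwise the configured fixed-effects estimator. The default fixed
estimator is Mantel–Haenszel with the Robins–Breslow–Greenland variance
— the convention of the era's standard software — with inverse variance
as an option; on the packaged data both agree to well under 0.01 on
every contrast. The random-effects estimator is DerSimonian–Laird, the
era-standard moment method; REML and profile-likelihood τ² are
deliberately not offered.

Continuity correction defaults to "halves-when-zero": 0.5 is added to
all four cells of a 2×2 table only when some cell is zero. The packaged
tables never hit a zero cell, so the default is inert there; the
"halves-always" and "none" policies are exposed for sensitivity work. A
table with an entire empty margin has no estimable odds ratio and is an
error under every policy. Stratified MH pooling itself uses raw counts —
it tolerates isolated zero cells as long as both cross-product sums are
positive.

## Hardy-Weinberg equilibrium and the quality rubric

Control arms are tested for HWE with the Pearson chi-square (1 df,
asymptotic, no continuity correction) against the expectations implied
by the sample allele frequency, at alpha 0.05. An exact test is out of
scope — the upstream literature records only a yes/no flag from the
asymptotic test, and every packaged control arm is comfortably in
equilibrium. Monomorphic arms return chi-square 0 with a warning rather
than an error, so a screening loop over many SNPs does not abort.

The quality rubric scores five categories — source of cases (0–3),
source of controls (0–3), genotyping specimen (0, 1 or 3), HWE in
controls (0 or 3), total sample size (0–3 in bands at 200, 500 and
1,000) — summing to 0–15, with ≥ 10 flagged high quality. Applied
strictly, the rubric gives Webb 11 where the source publication prints
12 (mixed cases 2 + volunteer controls 2 + mixed specimens 1 + HWE 3 +
n ≥ 1000 3); the package follows the rubric arithmetic and documents the
one-point discrepancy rather than reproducing it. The classification
(high quality) is unaffected.

## Publication bias

Egger's test regresses the standardized effects θᵢ/seᵢ on the
precisions 1/seᵢ by OLS and t-tests the intercept on k−2 df; it needs
k ≥ 3. Begg's rank-correlation test computes Kendall's τ (tau-b under
ties) between the variance-standardized deviates from the pooled
estimate and the sampling variances; its p-value is exact — full
permutation enumeration — for k ≤ 8, where the normal approximation is
at its worst and enumeration costs nothing, and a tie-corrected normal
approximation with continuity correction beyond. For the two 2-study
datasets these tests are reported as not estimable (an informative
error) rather than silently computed: at k = 2 Egger has zero residual
degrees of freedom, and any qualitative bias claim at that size is not
mathematically supportable. Funnel output is coordinates only (log OR
vs SE, pooled reference, 95% pseudo-confidence wedge); rendering is the
caller's concern.

## The simulator and what it does (not) show

`simulate_dataset()` draws control genotypes multinomially from HWE
proportions at variant allele frequency q, and case genotypes from the
same proportions tilted by per-genotype odds ratios (1, OR_het, OR_hom)
and renormalized — so the realized case-control odds ratio of each
genotype class against T1T1 converges to the nominal parameter, for the
recessive contrast too when OR_het = 1. Between-study heterogeneity,
when τ > 0, adds one Normal(0, τ²) draw per study to both log ORs, on
the same scale the random-effects model assumes. Reproducibility is by
a counter scheme: study i uses substream seed
(seed + 1000003·i) mod (2³¹−1), so any study can be regenerated alone.

Calibration choices, made once: recovery runs use a true homozygote OR
of 0.7 at q = 0.3 with 50 studies of 1,000 per arm and 500 replicates —
sizes chosen to match the effect size and per-study scale of the
packaged data while keeping the whole run in tens of seconds; the null
calibration of Egger's test uses k = 10 studies of 500 per arm and
1,000 replicates, a typical meta-analysis size where the test's
small-sample liberality is visible but mild. Observed on these runs:
mean pooled OR 0.6996, CI coverage 0.952, Egger type-I error 0.062
(`analysis/03_simulation_calibration.R` recomputes all three).

The simulator emulates multinomial sampling noise and log-scale
between-study heterogeneity only. Real data add genotyping error,
population stratification, linkage disequilibrium with causal variants,
covariate structure and selective publication — none of which it
models, so passing calibration shows the statistical machinery is
correct, not that any real dataset meets its assumptions.

## Numerical conventions and edge cases

- Display rounding is half-up (`round_half_up()`), matching how
  publication tables are typeset; base R's half-to-even would disagree
  on exact .005 boundaries. JSON output carries unrounded doubles.
- 2×2 cells are stored as doubles: cross-products of cohort-scale
  counts overflow 32-bit integers.
- Ties in Begg's statistic use the tau-b denominator; a zero denominator
  (all values tied) yields τ = 0.
- Egger's regression with all SEs equal has a constant regressor; the
  slope is then reported as `NA` and the intercept reduces to the mean
  standardized effect.
- `validate_dataset()` returns findings (study, field, message) instead
  of raising, so file-level QC can report everything at once;
  `meta_analyze()` refuses datasets with findings.

## Known limitations

No meta-regression, subgroup synthesis, Peto pooling, trim-and-fill, or
exact HWE test. The heterogeneity p-values printed in the source tables
for two rs861539 contrasts differ slightly from the IV-based Q used
here (a different software convention upstream); both lead to the same
fixed-effects selection, and the package asserts only the selection,
never those two printed p-values.
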