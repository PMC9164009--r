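---
title: "Two-sample Mendelian randomization with mrforge: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrforge)
```

## The problem

Observational associations between a biomarker and a disease are confounded
and can run in either direction. Mendelian randomization (MR) sidesteps both
problems by using genetic variants as instrumental variables: alleles are
assigned at conception, so a variant that raises a biomarker provides a
randomized "dose" of it. In the two-sample design, the variant-biomarker
associations come from one GWAS and the variant-disease associations from
another, and only summary statistics (per-allele beta, SE, allele
frequencies) are needed.

The motivating application is the question whether circulating C-reactive
protein (CRP), an inflammatory marker elevated in amyotrophic lateral
sclerosis (ALS) patients, *causes* ALS risk — or merely tracks the disease.
`mrforge` implements the complete workflow for this kind of analysis:
harmonization, the instrument QC cascade, six causal estimators,
pleiotropy/heterogeneity diagnostics and power.

A valid instrument must satisfy three assumptions: (1) *relevance* — it is
robustly associated with the exposure; (2) *independence* — it is not
associated with confounders of the exposure-outcome relation; (3)
*exclusion restriction* — it affects the outcome only through the exposure.
The package screens (1) with the per-variant F statistic, (2) with a
confounder-annotation filter, and probes violations of (3) with the
MR-Egger intercept, MR-PRESSO, and Cochran's Q.

## Harmonization

Both GWAS report effects relative to an "effect allele", but not
necessarily the same one, and possibly on opposite DNA strands. For every
variant shared by the two files, `harmonize()` aligns the outcome effect
onto the exposure's effect allele: a swapped allele pair negates the
outcome beta and complements its allele frequency; a strand mismatch for
non-palindromic pairs is resolved by base-complementing. A/T and C/G
(palindromic) pairs are strand-ambiguous; they can only be aligned through
allele-frequency concordance, which breaks down near 0.5. Variants whose
exposure EAF lies in the *intermediate band* are therefore excluded.

The band defaults to (0.42, 0.58) — the conventional 0.08 tolerance around
0.5. Published analyses that exclude "palindromic SNPs with intermediate
allele frequencies" rarely print the band they used, so this default is a
documented choice, configurable via `intermediate_eaf_band`. Palindromic
variants with a missing allele frequency are excluded conservatively.
Variants absent from the outcome study are dropped with a logged reason; no
proxy search against an external LD reference is attempted, since that
would require a web service, and the analyses this package reproduces
ultimately dropped such variants too.

## The instrument QC cascade

* **LD clumping** (`clump()`): greedy — keep the smallest-p variant,
  discard everything within 10,000 kb at r² > 0.001, repeat. The LD matrix
  is an input; a missing within-window pair is a hard error rather than an
  assumed zero.
* **Confounder filter** (`confounder_filter()`): a variant is excluded iff
  a local annotation table links it to a screened trait at p < 5 × 10⁻⁸
  (strict inequality). The default trait list covers lipids, type 2
  diabetes, childhood BMI, blood-cell counts and blood pressure — traits
  with reported causal links to ALS — and is configurable.
* **Steiger directionality** (`steiger_filter()`): a variant should explain
  more variance in the exposure than in the outcome. Variance explained is
  2β²·MAF(1−MAF) on each side, each with its own study's allele frequency
  and sample size; a Fisher-z test on the implied correlations is reported
  alongside. Ties count as failures (the exclusion rule targets
  "direction = FALSE", and exact ties essentially never occur in float
  inputs). Applying the standardized-trait formula to the outcome's
  log-odds betas is an approximation; `r2_fun_out` is the hook for a
  liability-scale alternative.
* **Weak instruments** (`f_filter()`): F = β²/se², excluding F < 10.

## The estimators

With Wald ratios $\hat\beta_j = \beta_{Y,j}/\beta_{X,j}$ and outcome-side
weights $w_j = 1/\mathrm{se}_{Y,j}^2$:

* **IVW** is the zero-intercept weighted regression of outcome on exposure
  betas, equivalently the inverse-variance-weighted mean of the Wald
  ratios. The default *multiplicative random-effects* model inflates the
  fixed-effect SE by $\sqrt{Q/(L-1)}$, floored at 1, where Q is Cochran's
  heterogeneity statistic about the pooled estimate; the floor prevents
  heterogeneity *deficits* from shrinking the SE. Inference is normal.
* **MR-Egger** adds an intercept, which estimates average directional
  pleiotropy under the InSIDE assumption (instrument strength independent
  of direct effects); instruments are first oriented so every exposure
  beta is positive, since the intercept is not invariant to per-variant
  sign flips. Residual overdispersion scales the coefficient covariance by
  max(1, Q′/(L−2)), and both coefficients use t(L−2) reference
  distributions — with L = 4 instruments that is t(2), and the difference
  from a normal reference is large (a |t| of 2.2 is p ≈ 0.16, not 0.03).
* **Weighted median**: order the Wald ratios, form cumulative weight
  midpoints, interpolate at 0.5. Consistent while valid instruments carry
  more than half the weight.
* **Simple/weighted mode**: the argmax of a normal-kernel density of the
  ratios, unweighted or inverse-variance weighted. Bandwidth is
  φ · 0.9 · min(sd, MAD) · L^(−1/5) with φ = 1 by default; the MAD guards
  against outlier-inflated bandwidths, and φ trades robustness against
  efficiency.
* **Wald ratio** for single-instrument analyses, with the first-order
  delta-method SE se_out/|β_exp| by default. The first-order form ignores
  exposure-side uncertainty; it is what standard MR software reports and
  what reproduces published single-SNP CIs, and with F ≫ 10 the
  second-order correction (available via `second_order = TRUE`) is
  negligible.

Median and mode SEs come from a parametric bootstrap (resampling both
betas from their sampling distributions; default 1000 draws, explicit seed
required). CIs are 95% by default (z = 1.96, or t(L−2) for Egger).

`mr_fit()` bundles whichever estimators the instrument count admits into
one object with `print`/`summary`/`coef`/`confint`/`plot`/`residuals`
methods.

## MR-PRESSO

`mr_presso()` tests for pleiotropy through residuals: each variant's
squared weighted residual from its *leave-one-out* IVW prediction is
summed into an observed RSS, which is referred to a null distribution
built by simulating datasets from the leave-one-out predictions and the
reported SEs (the leave-one-out bookkeeping variant is named in the output,
since a single-fit variant also circulates). Empirical p-values use the
(k+1)/(n+1) convention, so the global p can never be exactly zero and is
floored at 1/(n_sim+1). Per-variant outlier p-values are
Bonferroni-adjusted across instruments (configurable in principle, matching
common practice); flagged outliers trigger an outlier-corrected IVW refit
and a distortion test whose null resamples random same-size removals.
Default n_sim is 1000. All resampling is driven by one explicit seed and
reruns are bit-identical.

## Power

For a binary outcome, the package uses the standard normal-approximation
power formula driven by the noncentrality
$\sqrt{N\,R^2\,K(1-K)}\,|\ln \mathrm{OR}|$, with K the case fraction and
R² the variance of the exposure explained by the instrument set.
`detectable_or()` inverts it by monotone root-finding (relative tolerance
1e-8). Web calculators in circulation implement slight variants of this
family; the formula used here is stated in this section and in the
function documentation precisely so its results can be compared against
them — agreement to within about 0.01 on the OR scale is typical, exact
agreement is not expected.

## The synthetic-data generator

`synth_generate()` draws paired summary statistics under the generative
model the estimators assume: true exposure effects γⱼ (uniform in
[0.5, 1.5] × scale), outcome effects θγⱼ + αⱼ, observed betas equal to the
truths plus normal noise at the summary-statistic SEs implied by allele
frequency and sample size — se ≈ 1/√(2·MAF(1−MAF)·n) for the standardized
exposure and the K(1−K)-deflated analogue for the log-odds outcome. Direct
effects αⱼ are zero, balanced, or directional, optionally correlated with
γⱼ to violate InSIDE. Planted structure (intermediate-frequency
palindromes, confounder-annotated variants, LD blocks) exercises every
filter, and the truth record stores θ, γ, α and the intended filter fates.

Defaults mirror the CRP-ALS study conditions: n_exp = 204,402,
n_out = 80,610 with 20,806 cases, MAF in 0.05–0.5, and an exposure effect
scale of 0.1 — the magnitude of published per-allele CRP-locus effects —
which makes instruments strong (F in the hundreds, unambiguous Steiger
direction), matching the reported state of the real instrument sets after
QC. The generator emulates *independent* instruments with normal sampling
noise and exact SEs; it does not emulate sample overlap between the two
GWAS, LD beyond the planted blocks, allele-frequency mismatch between
studies, or winner's-curse selection. Simulation results therefore
validate the estimators under their stated assumptions, not robustness to
those additional real-data features.

## Verification problem sizes

The test suite validates the statistical properties at sizes chosen to
make Monte-Carlo error small relative to the tested margins while keeping
the default run in the minutes range: estimator coverage on 500 replicates
of 20-instrument datasets (bootstrap SEs at 200 draws, ample for an SE
entering a coverage count); MR-PRESSO size on 500 replicates at n_sim =
1000; planted-outlier detection on 20 replicates; weighted-median vs IVW
bias under 40% directional pleiotropy on 200 replicates; and
estimator-vs-WLS-oracle agreement at 1e-10 on 50 random 3–10 instrument
sets.

## Known limitations

* Correlated instruments are only handled by exclusion (clumping), not by
  a generalized-least-squares IVW.
* The Steiger outcome-side R² uses the standardized-trait formula on
  log-odds betas (see above).
* No multivariable MR, no robust-regression or contamination-mixture
  estimators.
* Multiple-testing correction across the estimator panel is deliberately
  not applied; the panel is read as sensitivity analyses around the IVW
  primary, consistent with the analyses this package reproduces.
* The reverse-direction (outcome → exposure) pipeline flag exists but
  refuses to run: a meaningful reverse analysis needs an instrument set
  for the outcome, and the motivating application had a single eligible
  variant, too little for any estimator beyond a lone Wald ratio.

## A worked example

```{r example, eval = FALSE}
fx <- table1_fixture()          # 4 conservative CRP-locus instruments
h <- harmonize(fx$exposure, fx$outcome)
fit <- mr_fit(h, seed = 1)
fit
summary(fit)
cochran_q(h$instruments, fit$estimates$ivw)
detectable_or(n_total = 80610, case_fraction = 20806 / 80610,
              r2 = 0.0155, alpha = 0.05, target_power = 0.80)
```
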