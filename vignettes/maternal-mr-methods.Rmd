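---
title: "Maternal Mendelian randomization with mother-offspring duos: models and design choices"
author: "duoMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal Mendelian randomization with mother-offspring duos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duoMR)
```

## The problem

Observational associations between a maternal exposure measured in (or
around) pregnancy and an offspring outcome such as birthweight are prone to
confounding: anything that raises, say, maternal serum urate and
independently lowers birthweight will masquerade as an intrauterine effect.
Mendelian randomization (MR) replaces the measured exposure with genetic
variants that proxy it. Because alleles segregate randomly, the variants are
independent of the classic confounders, and a causal effect of the exposure
should reappear as a proportional effect of the variants on the outcome.

Maternal-exposure MR carries an extra hazard that ordinary two-sample MR
does not: the mother transmits half her alleles to the child. A maternal
instrument therefore has a second, *fetal* route to the outcome — the
child's own genotype — which violates the exclusion restriction. duoMR
implements the complete workflow for this setting:

1. **Harmonization** of exposure and outcome GWAS summary statistics to a
   common effect allele, with LD-proxy substitution for missing variants.
2. **Instrument diagnostics**: per-SNP variance explained, mean F,
   Cochran's Q.
3. **Maternal/fetal partitioning** of birthweight GWAS effects (the
   weighted-linear-model structural equations), which removes the fetal
   route.
4. **Two-sample MR estimators**: fixed-effects IVW, MR-Egger, weighted and
   penalized weighted median, leave-one-out and SNP-exclusion sensitivity
   analyses.
5. **One-sample 2SLS** with a standardized genetic-score instrument, and a
   product-of-paths **mediation expectation**.
6. A **mother-offspring duo simulator** that generates every input the
   pipeline consumes, so the whole chain is testable without any external
   data.

## The structural model

Write $G_M$ and $G_{Off}$ for maternal and offspring effect-allele dosages
at a SNP. An individual's own outcome associates with their own genotype
through the fetal effect $\beta_F$ plus, because $\mathrm{corr}(G_M,
G_{Off}) = 1/2$ under Mendelian transmission, half the maternal effect; a
mother's genotype associates with her child's outcome through $\beta_M$
plus half the fetal effect:

$$E[\beta_{own}] = \beta_F + \tfrac12 \beta_M, \qquad
  E[\beta_{offspring}] = \beta_M + \tfrac12 \beta_F.$$

`wlmPartition()` inverts this two-equation system per SNP:

$$\beta_M = \tfrac{4\beta_{offspring} - 2\beta_{own}}{3}, \qquad
  \beta_F = \tfrac{4\beta_{own} - 2\beta_{offspring}}{3},$$

with variances from the same linear combination, e.g. $\mathrm{var}(\beta_M)
= (16\,v_{offspring} + 4\,v_{own} - 16\,\mathrm{cov})/9$. The inversion is a
linear bijection (`wlmRecompose()` restores the inputs exactly). The
covariance term matters only when the two birthweight GWAS share samples;
`duoEffectCovariance()` computes it for fully overlapping duo data, and the
default of zero matches non-overlapping consortium samples. The published
two-sample application this package is built around had about 1.7% overlap
between its exposure and outcome samples, small enough to ignore; we adopt
the same default. We implement the identification equations only, not the
original estimator's generalized-least-squares pooling across partially
overlapping sub-samples — the equations are what the synthetic pipeline
needs to be self-contained.

Using the maternal-specific effects $\beta_M$ as the MR outcome is what
keeps the fetal genome from contaminating the causal estimate.

## Estimators

With harmonized per-SNP pairs $(\hat\beta_{x,j}, \hat\beta_{y,j})$ and
first-order weights $w_j = 1/\mathrm{se}(\hat\beta_{y,j})^2$:

* **IVW (fixed effects)** is the zero-intercept weighted regression
  $\hat\theta = \sum w_j \hat\beta_{x,j}\hat\beta_{y,j} / \sum w_j
  \hat\beta_{x,j}^2$, with $\mathrm{se} = (\sum w_j
  \hat\beta_{x,j}^2)^{-1/2}$ and a normal reference. With one SNP it is the
  ratio estimate.
* **MR-Egger** frees the intercept; the slope is the causal estimate under
  the InSIDE assumption and a non-null intercept indicates unbalanced
  horizontal pleiotropy. Instruments are oriented so all
  $\hat\beta_{x,j} \ge 0$ first. Inference is on $t_{J-2}$ with a
  multiplicative residual dispersion floored at 1, so balanced pleiotropy
  (which inflates residual scatter beyond the fixed-effect weights) widens
  the intervals rather than breaking the intercept test.
* **Weighted median**: per-SNP ratios $r_j = \hat\beta_{y,j} /
  \hat\beta_{x,j}$ with weights $\hat\beta_{x,j}^2 /
  \mathrm{se}(\hat\beta_{y,j})^2$ (first-order inverse ratio variance); the
  estimate interpolates the weighted empirical CDF at probability 0.5. The
  SE is a parametric bootstrap (betas resampled from their sampling
  normals), with a mandatory explicit seed; the default is 1000 replicates.
* **Penalized weighted median** multiplies each weight by
  $\min(1, 20\,p_j)$ where $p_j$ is the one-df chi-square tail of the SNP's
  heterogeneity contribution about the weighted median — outlying ratios
  are shrunk, concordant sets are untouched (the estimator then equals the
  plain weighted median exactly).
* **2SLS** (`tsls()`): exposure regressed on the standardized genetic score,
  outcome on the fitted values, SEs from the standard IV variance with
  residuals formed against the observed exposure; the first-stage F is
  reported and a flat first stage is an error, not a number.

Ratio-variance weighting uses first-order (outcome-only) delta weights
throughout, the choice consistent with fixed-effects IVW; Cochran's Q is
computed about the fixed-effects IVW fit with the same weights, on $J - 1$
df, and the output records the weighting scheme. The mediation expectation
is the product of paths $a \times b$ (exposure to mediator, mediator to
outcome) with the first-order delta-method SE $\sqrt{a^2\mathrm{se}_b^2 +
b^2\mathrm{se}_a^2}$ — an informal expectation under *full* mediation, not
a formal mediation analysis.

## The duo simulator and its defaults

`simulateDuos()` generates the causal chain the pipeline is designed to
recover: urate (SD units) → systolic blood pressure (SD units) →
birthweight (grams), with maternal-specific and fetal-specific genetic
effects and a shared latent confounder. Defaults are the study conditions
the package targets:

| parameter | default | rationale |
|---|---|---|
| `n_snps` | 114 | independent urate instruments in the source GWAS |
| `target_r2_exposure` | 0.064 | the 114 SNPs explain 6.4% of urate variance |
| `var_y_exposure` | 1.767 | urate phenotypic variance on the measurement scale (display only; all estimation runs in SD units) |
| `a_urate_to_sbp` | 0.07 | SD SBP per SD urate (1.7 mmHg against SD(SBP) = 24.23 mmHg) |
| `sd_sbp_mmHg` | 24.23 | SD of SBP |
| `b_sbp_to_bw` | −12/0.07 ≈ −171.4 g per SD SBP | back-derived from the two published path quantities: a full-mediation expectation of about −12 g at a = 0.07. The source reports this path only in supplementary material, so the default is the package's own calibration and should be overridden when a directly estimated value is available |
| `direct_urate_to_bw` | 0 | full mediation by SBP is the default scenario |
| `fetal_effect_sd` | 5 g/allele | modest fetal genetic effects on birthweight |
| `confounder_on_exposure`, `confounder_on_bw` | 0.3 SD, −55 g | one standard-Gaussian latent with loadings sized so the observational association (≈ −12 + 0.3×(−55) ≈ −28 g/SD) is biased well away from the causal −12 g/SD, reproducing the qualitative observational-vs-MR contrast the design exists to expose |
| `maf_range` | (0.05, 0.5) | common variants, as GWAS instruments are |
| `bw_mean`, `bw_resid_sd` | 3500 g, 440 g | total birthweight SD ≈ 477 g once the modelled paths are added |

Offspring genotypes are one allele transmitted from the mother (Bernoulli
$g_M/2$ per locus) plus one paternal allele drawn from the population
frequency — fathers are otherwise unmodelled, which is adequate because the
partition uses only own/offspring GWAS pairs. Per-SNP exposure weights are
drawn and rescaled so the genetic variance share equals
`target_r2_exposure` exactly. Pleiotropic (direct genotype-to-outcome)
effects are oriented to the exposure-raising allele, so a mean-zero
distribution is balanced (InSIDE-satisfying) and a non-zero mean is
directional. Allele labels are sampled over all ordered pairs, so a
realistic fraction of instruments is strand-ambiguous and exercises the
palindrome screen. A fixed seed makes the cohort and all derived tables
byte-identical; every stochastic routine in the package either requires an
explicit seed or restores the caller's RNG state.

What the simulator does *not* emulate: linkage disequilibrium between
instruments (the source SNP set is independent by construction),
non-European allele-frequency spectra, assortative mating, gestational-age
modelling, and measurement error in the exposure. Passing tests therefore
show the estimators are correct under the stated generative model, not that
any particular real-data estimate is right.

## Harmonization and numerical choices

* **Palindromic SNPs** (A/T, G/C) are dropped when $\min(\mathrm{eaf},
  1-\mathrm{eaf}) > 0.42$ — a common screening convention; the threshold is
  configurable because curated instrument lists may make the screen
  unnecessary. Retained palindromes are oriented by allele frequency when
  both tables carry one, otherwise by the reported allele labels. A missing
  outcome frequency is permitted; screening then uses the exposure
  frequency alone.
* Harmonization keys on rsid, not position; coordinates are carried as
  1-based GRCh37 metadata.
* **Proxy substitution** takes the highest-$r^2$ available proxy at
  $r^2 \ge 0.8$ by default, breaking exact ties lexicographically by rsid
  (deterministic output); targets without a qualifying proxy are excluded
  and reported.
* Accounting invariant everywhere: retained + dropped = intersection, and
  every exclusion carries a reason string.
* Missing genotype dosages are mean-imputed per SNP before scoring;
  all-missing SNPs are excluded with a warning. Scores are standardized
  against the analysis sample's own mean and SD.
* Monomorphic SNPs yield undefined regression betas and are excluded from
  derived summary tables with a per-row report.
* The observational stage uses listwise deletion with logged counts, and a
  rank-deficient design is an error naming the collinear columns.
* The per-SNP F statistic is $(\hat\beta_x/\mathrm{se}_x)^2$, the standard
  summary-data approximation; in expectation it equals
  $1 + n r^2/(1-r^2)$, which the tests verify at two sample sizes.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on simulated data,
at sizes chosen to keep Monte-Carlo error a small fraction of the effects
under test: super-cohorts of 40,000–200,000 duos split into non-overlapping
exposure and outcome samples for the recovery checks, 1000 summary-level
replicates for the type-I-error checks, 250 replicate cohorts (8 SNPs x
1500 duos) for the partition-coverage check, and 20,000 duos for the
simulator-calibration checks (mother-offspring dosage correlation 0.5 ±
0.02; exposure $R^2$ = 0.064 ± 0.01). At the acceptance script's scale the
IVW standard error is 8–9 g per SD, comparable to the source analysis.

## Known limitations

* **The weighted median under heavy one-sided contamination.** The
  estimator's guarantee concerns valid *weight* share, and it is a
  guarantee about consistency, not finite-precision unbiasedness: with 40%
  of the weight shifted one way, the estimate is the ~0.83 quantile of the
  valid ratio distribution, displaced from the truth by roughly one pivotal
  ratio standard error. When per-SNP ratio noise is large relative to the
  causal effect — exactly the situation for a −12 g/SD effect instrumented
  by SNPs explaining 0.06% of exposure variance each — that displacement
  can exceed the bootstrap SE. The robustness contrast (median stays put,
  IVW shifts) is therefore demonstrated in the estimator's operating
  regime: strong instruments with the invalid minority carrying a minority
  of the weight.
* The Egger intercept test assumes InSIDE; directional pleiotropy
  correlated with instrument strength defeats it.
* Fixed-effects IVW is the only IVW flavour implemented; under real
  heterogeneity its intervals are anti-conservative (the Q statistic is
  reported precisely so this is visible).
* When both birthweight GWAS derive from the same duos and the sampling
  covariance is left at zero, partitioned SEs are conservative and Q is
  correspondingly deflated; supply `duoEffectCovariance()` in that case.
* The mediation expectation is a plug-in product of paths; it propagates
  path uncertainty by the delta method but is not a formal mediation
  analysis.

## End-to-end use

```{r pipeline, eval = FALSE}
cfg_sim <- duoSimConfig(n_duos = 40000, seed = 7)
cohort <- simulateDuos(cfg_sim)
s1 <- cohort[, 1:20000]        # exposure-GWAS sample
s2 <- cohort[, 20001:40000]    # outcome-GWAS duo sample

exposure <- cohortSummaryStats(s1)$exposure
outcomes <- cohortSummaryStats(s2)

cfg <- mrAnalysisConfig(
  exposure = exposure,
  own_bw = outcomes$own_bw, offspring_bw = outcomes$offspring_bw,
  cohort = s1, seed = 7, out_dir = "results")
report <- runPipeline(cfg)
report
```

The report's provenance block (config hash, seed, input checksums, package
version) is sufficient to reproduce every number in it; running the same
config twice yields identical reports.
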