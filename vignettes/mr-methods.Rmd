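---
title: "Methods: one- and two-sample Mendelian randomization in mrcausal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one- and two-sample Mendelian randomization in mrcausal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcausal)
```

## The problem

Observational associations between a common binary condition (the
motivating case is migraine) and a continuous health outcome (a 0–30
cognitive screening score, 30 best) are confounded by lifestyle,
medication and reverse causation. Mendelian randomization (MR) uses
genetic variants as instrumental variables: alleles are assigned at
meiosis independently of later confounders, so a variant that is (i)
associated with the exposure, (ii) independent of confounders, and (iii)
associated with the outcome only through the exposure identifies a
causal effect.

`mrcausal` implements the three classical designs over a common set of
primitives:

1. **PRS / 2SLS (one sample).** Selected SNPs are combined into one
   polygenic risk score `PRS_i = sum_j gamma_j G_ij`, where `G_ij`
   counts effect alleles and the weights are the joint regression
   coefficients of the exposure on all dosages. The outcome is regressed
   on the fitted score; the slope is the causal estimate. Instrument
   strength is summarised by the F statistic of the exposure-on-score
   regression, with `F < 10` (strict) flagging a weak instrument.
2. **Summary MR, one sample.** Per-SNP exposure (`gamma_j`) and outcome
   (`Gamma_j`) associations estimated in the same cohort are combined by
   the inverse-variance weighted (IVW) estimator, MR-Egger, and the
   weighted median.
3. **Summary MR, two samples.** The same estimators applied to
   associations from two disjoint cohorts.

## Per-SNP ratios and their orientation

Each instrument's causal estimate is the Wald ratio
`beta_j = Gamma_j / gamma_j` — outcome association over exposure
association. This is the standard orientation: the units
(outcome units per exposure unit) only come out right this way, and the
package states it explicitly in its documentation because the reciprocal
is occasionally (and confusingly) written in applied reports. The
default standard error is the first-order delta approximation
`se(Gamma_j)/|gamma_j|`; a second-order version that adds the
`se(gamma_j)` term is available (`wald_ratios(..., second_order =
TRUE)`). SNPs with `gamma_j = 0` are excluded with an audit record, not
silently kept.

## Estimators

**IVW.** `beta = sum(w_j beta_j)/sum(w_j)` with `w_j = 1/se_j^2`;
algebraically the slope of a weighted through-origin regression of
`Gamma` on `gamma` with weights `1/se(Gamma_j)^2` (a property the test
suite checks against an independent regression). The fixed-effect SE is
`(sum w_j)^(-1/2)`; the multiplicative random-effects SE scales it by
`max(1, sqrt(Q/(k-1)))` with Cochran's `Q`, never below the fixed SE.
The fixed-effect estimate is the headline and the random-effects
estimate is always computed alongside.

**MR-Egger.** After orienting every SNP so `gamma_j >= 0`, a weighted
regression of `Gamma` on `gamma` *with a free intercept*; the slope is
the causal estimate and the intercept estimates average directional
pleiotropy. Egger regression is exquisitely sensitive to noise in the
exposure associations (regression dilution); the `I2GX` statistic
quantifies this:

    I2GX = max(0, (Q_GX - (k - 1)) / Q_GX),
    Q_GX = sum v_j (|gamma_j| - gbar)^2,  v_j = 1/se(gamma_j)^2.

`I2GX < 0.90` corresponds to more than about 10% relative bias, and the
package then flags the Egger estimate invalid — it is still reported,
with the flag, rather than omitted, so a reader can see what was gated
and why.

**Weighted median.** The 50% point of the weight-ordered ratios
(cumulative weight midpoints, linear interpolation at 0.5). It is
consistent whenever valid instruments carry more than half the weight,
making it the robustness check against a pleiotropic minority. Its SE
comes from a seeded parametric bootstrap (default 1000 replicates)
redrawing each association from a normal centred at its estimate; the
bootstrap was chosen because no closed-form SE is exact for the
interpolated median and the procedure is transparent and reproducible.

**Sensitivity analyses.** Funnel outliers are ratios more than three
interquartile ranges outside the quartiles (interpolated order
statistics, R's default quantile definition; the rule needs at least 5
SNPs and is reported not-applicable below that). Leave-one-out
re-estimates with each SNP removed and flags exclusions that move the
estimate outside the full-set 95% CI. All CIs are normal-based
`beta -/+ 1.96 se`.

## The synthetic cohort generator

Real biobank genotypes and a versioned external GWAS database are
access-restricted, so the package carries a seeded generator that
emulates the statistical structure the analysis assumes:

* **Genotypes.** Each genotype is the sum of two haplotypes. Within an
  LD block, haplotype alleles are a latent equicorrelated Gaussian
  (correlation `rho`) thresholded at the MAF quantile — Hardy–Weinberg
  proportions per SNP, tunable pairwise r², independence across blocks.
  This is deliberately not a realistic human LD map: the pipeline only
  needs LD for clumping to act on.
* **Exposure.** A liability-threshold model:
  `L = sum_j gamma_j (G_j - 2 maf_j) + c_x C + eps_x` with the residual
  scaled so `Var(L) = 1`, and case status `L > qnorm(1 - k)` at
  prevalence `k` (default 0.15).
* **Outcome.** `mu0 + beta L + sum_j alpha_j G_j + c_y C + noise`,
  with MMSE-like defaults: bounds 0–30, target mean 27, noise SD 2.4.
  Clipping to the bounds and rounding to integers are off by default
  because they break the exact linear identities the estimator tests
  rely on; realism fixtures turn them on.
* **Pleiotropy presets.** `none`, `balanced` (`alpha ~ N(0, tau)`), and
  `directional` (`alpha ~ N(mu, tau)`, default `mu = 0.05`,
  `tau = 0.02`) applied to a stated fraction of SNPs (default 30%).
* **Defaults.** 18 independent loci with per-allele liability effects
  drawn uniformly from 0.05–0.15 and MAFs from 0.10–0.50 — small
  effects, as expected for a polygenic trait with ~18 usable
  instruments.

What the generator does *not* emulate: realistic LD decay, imputation
error, array QC artefacts, population stratification, assortative
mating. Passing tests therefore show the estimators behave correctly
under the model's assumptions, not that those assumptions hold in any
particular biobank.

## Exposure scale: liability versus case status

The configured causal effect acts on the continuous liability, not on
the binary indicator. Consequently:

* exposure associations estimated on the **liability** give Wald-ratio
  estimands exactly equal to the configured effect (this is the scale
  the recovery tests use);
* exposure associations estimated on the **binary indicator** are
  attenuated by roughly `phi(Phi^-1(1 - k))` (about 0.23 at prevalence
  0.15), so the ratio estimand is *amplified* by its reciprocal. A
  real one-sample study regressing case status inherits this scale, and
  the analysis scripts show both so the difference is visible rather
  than mysterious.

The stage-1 family for the PRS is the linear-probability model by
default: two-stage least squares and the additive PRS formula
presuppose a linear first stage. Logistic stage 1 is available for
exploration, with the caveat that the fitted score then lives on the
log-odds scale.

## Instrument selection and harmonization

Selection filters exposure records at genome-wide significance
(strict `p < 5e-8`), then applies PLINK-style greedy clumping: sort
candidates with `p < 1e-5` by p-value (ties by position, then id);
repeatedly take the best as index and prune candidates within a
10,000 kb window (inclusive) on the same chromosome with `r^2 >= 0.001`
against a user-supplied genotype reference — the package deliberately
takes its LD from a local reference rather than an external service.
Applying the significance filter first makes the index threshold
vacuous in the default pipeline, but both thresholds stay configurable
because they are logically distinct knobs. Equal p-values are broken by
position then id so the output is reproducible and independent of input
record order.

Harmonization matches records by SNP id and aligns the outcome to the
exposure's effect allele: swapped alleles flip the sign and complement
the frequency; A↔T/C↔G complements handle strand swaps. Palindromic
SNPs are strand-ambiguous; the default drops them when the outcome EAF
is within 0.42–0.58 and otherwise aligns by frequency (the band is the
widely used convention; the underlying study is silent on its choice,
which is why every drop carries a reason code in the audit table —
`retained + dropped = input` always).

## Numerical choices and degenerate inputs

* Ties in PRS tertile assignment: ranked assignment with ties broken by
  original index (lower index to the lower tertile), guaranteeing group
  sizes differ by at most one while staying deterministic.
* Constant variables in the tertile table get `NA` p-values rather
  than 1; monomorphic SNPs and exact fits in the GWAS scan are flagged
  `degenerate` and excluded downstream.
* The fitted PRS can be carried at a fixed number of decimals
  (half-even rounding), mirroring workflows that export the score at
  four decimals; on a study-sized cohort this moves the 2SLS slope by
  less than 1e-2 (tested).
* GWAS p-values use the normal approximation (`2 pnorm(-|beta/se|)`),
  kept mutually consistent with beta and SE.
* The Egger SE uses multiplicative random effects bounded below at the
  fixed-effect scale; exact-fit fixtures keep the OLS scale so
  machine-precision identities hold.
* Two cohorts of a two-sample study must use different seeds; a shared
  seed is an error, not a warning, because it silently destroys the
  independence the design is named for.

## Simulation sizes and what the calibration shows

The calibration suite uses 100 replicates at n = 20,000 per cohort for
parameter recovery, 500 replicates at n = 5,000 for type-I error, and
200 replicates for the pleiotropy scenario — sizes chosen to keep
Monte-Carlo error a small fraction of the tolerance being checked.

Two honest findings about fixed-effect IVW under these conditions are
worth stating because the package reports them rather than hiding them.
First, with liability effects as small as 0.05 and n = 20,000, the
first-order delta SE omits a non-negligible `se(gamma)` term and
marginal GWAS estimates from a single cohort are mildly positively
correlated across SNPs through the shared polygenic signal; both shrink
the nominal CI, and measured coverage of the fixed-effect IVW CI is
around 85–90% rather than 95%. The multiplicative random-effects SE
(always reported) recovers most, not all, of the gap. Second, under the
directional-pleiotropy preset (30% invalid SNPs, mean direct effect
0.05) the induced IVW bias (~+0.1) is comparable to one sampling SD, so
although the weighted median is less biased on average, it wins the
per-replicate absolute-error comparison only modestly more than half
the time; its robustness advantage becomes decisive as the pleiotropic
effects grow relative to sampling noise. Both behaviours are properties
of the estimators under these conditions, not implementation artefacts:
the point estimates match independent closed-form oracles to 1e-9 and
the mean recovery bias is below 0.05.

## Known limitations

* No proxy-SNP lookup, multi-allelic variants, or PLINK binary formats.
* No MR-PRESSO, mode-based estimators, multivariable MR, or Steiger
  filtering.
* The OR scale on a continuous-outcome beta reproduces a reporting
  convention; `beta_to_or` performs the arithmetic without endorsing
  the interpretation.
* Covariate adjustment in the 2SLS stages is available in the GWAS scan
  but the headline estimator follows the unadjusted design, relying on
  the instrument-confounder independence the design assumes.

## A worked miniature

```{r}
panel <- default_panel(18, seed = 3)
cfg_exp <- cohort_config(n_individuals = 4000, causal_beta = 2.4, seed = 1)
cfg_out <- cohort_config(n_individuals = 4000, causal_beta = 2.4, seed = 2)
study <- simulate_two_sample_study(panel, cfg_exp, cfg_out)
iset <- harmonize_instruments(study$exposure_stats, study$outcome_stats)
report <- mr_report(iset, seed = 7)
report$headline[, c("method", "beta", "ci_low", "ci_high", "valid")]
```
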