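---
title: "Two-sample Mendelian randomization with mrpipe: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
library(dplyr)
```

## The problem and the model

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure on an outcome from
observational data.  Because alleles are assigned at conception,
essentially at random with respect to later-life confounders, a variant
that robustly alters the exposure acts like a randomized nudge: if the
exposure causes the outcome, variant carriers should show a proportional
shift in the outcome.  The motivating application for this package is
maternal central obesity — waist-to-hip ratio, waist circumference, and
hip circumference, each adjusted for BMI — as the exposure, and offspring
birth size (birth weight, birth length, head circumference, pubertal
height) as outcomes, using only published GWAS summary statistics from
large consortia rather than individual-level genotypes.

In the two-sample setting, variant–exposure associations
$(\hat\beta_{Xj}, \sigma_{Xj})$ come from one GWAS and variant–outcome
associations $(\hat\beta_{Yj}, \sigma_{Yj})$ from another,
non-overlapping one.  Under a linear causal model with effect $\beta$,
each valid instrument $j$ satisfies
$\mathbb{E}[\hat\beta_{Yj}] = \beta\,\gamma_j$ where $\gamma_j$ is the
true variant–exposure effect.  Validity requires the three classic IV
assumptions: association with the exposure, independence from
confounders, and no effect on the outcome except through the exposure
(no horizontal pleiotropy).

The per-variant (Wald) ratio estimate is
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order standard
error $\sigma_{Yj}/|\hat\beta_{Xj}|$, giving inverse-variance weight
$w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$.  Three estimators combine the
ratios:

* **IVW** (primary): $\hat\beta = \sum_j w_j\hat\theta_j / \sum_j w_j$,
  standard error $(\sum_j w_j)^{-1/2}$.  Algebraically identical to
  weighted least squares of $\hat\beta_Y$ on $\hat\beta_X$ through the
  origin with weights $1/\sigma_Y^2$, and, for uncorrelated variants,
  to two-stage least squares on individual-level data.  Consistent only
  when *every* instrument is valid.
* **Weighted median** (sensitivity): the median of the ratio
  distribution in which each $\hat\theta_j$ carries mass
  $w_j/\sum w$; computed by linear interpolation of the standardized
  cumulative weights $s_j = \sum_{k\le j} w'_k - w'_j/2$ to $s = 0.5$
  after ordering the ratios.  Consistent when instruments carrying more
  than half the weight are valid.  Its standard error comes from a
  parametric bootstrap (resample each $\hat\beta_X$, $\hat\beta_Y$ from
  a normal centred at the observed value with the reported SE and
  recompute).
* **MR-Egger** (sensitivity): weighted regression of $\hat\beta_Y$ on
  $\hat\beta_X$ *with* an intercept, after orienting every instrument so
  $\hat\beta_X \ge 0$.  The slope is a pleiotropy-corrected causal
  estimate; the intercept estimates the average direct (pleiotropic)
  effect, and an intercept distinct from zero is evidence against the
  exclusion restriction.  Interpretability of the intercept rests on the
  InSIDE condition — direct effects uncorrelated with instrument
  strength.

## Fixed analysis conventions

These choices are deliberate and uniform across the package:

* **IVW weights and SEs.**  Fixed-effect weights
  $\hat\beta_X^2/\sigma_Y^2$, first-order delta-method SEs that ignore
  $\sigma_X$ (the standard summary-data IVW).  No random-effects
  variant is provided.
* **Reference distributions.**  IVW and weighted-median inference use
  normal quantiles; MR-Egger uses $t_{m-2}$ for both slope and
  intercept, with the weighted-regression residual SD floored at 1 so
  the residual variance is never deflated below the reported
  $\sigma_Y$.  Published analyses do not always state their p-value
  conventions; ours are documented here and applied consistently rather
  than matched to any particular table.
* **CI multiplier.**  The exact 0.975 quantile (1.959964…), not 1.96.
* **Threshold comparisons are strict**: instruments require
  $p < 5\times10^{-8}$; LD pruning discards $r^2 > 0.05$ (keeping, per
  correlated group, the smallest p-value, ties broken lexicographically
  by variant id so results are independent of row order); a proxy needs
  $r^2 > 0.8$.
* **Unknown LD is treated as independence.**  Pairwise $r^2$ comes from
  a user-supplied table; services that report LD typically return only
  linked pairs, so an absent pair is read as "unlinked".  A `strict`
  flag turns an unknown pair among candidate instruments into an error
  instead.
* **Proxy pool.**  A proxy must appear in *both* the exposure and the
  outcome tables (an effect estimate is needed on each side) and must
  not already be an instrument (no variant is double-counted).
* **Palindromic variants** (A/T, C/G) cannot be strand-resolved from
  allele letters: the swap and strand-flip readings coincide.  The
  default policy drops them — the conservative reading of
  effect-allele matching.  `palindromic_policy = "infer-by-eaf"`
  instead orients them by allele frequency when both studies'
  frequencies are farther than `eaf_tolerance` (default 0.08) from
  0.5; frequencies on the same side of 0.5 confirm the written
  orientation, opposite sides flip the sign, anything closer to 0.5 is
  dropped.  Harmonization never alters a standard error and drops
  rather than guesses; every decision lands in an audit table.
* **Bonferroni reporting.**  The per-exposure threshold is
  $\alpha/m$ with $m$ the *final post-harmonization* instrument count
  for that exposure–outcome pair (an analysis can equally be reported
  against the pre-harmonization count; the divisor used is logged with
  the run).  $0.05/25 = 0.002$; $0.05/41 = 0.00122$ at 3 significant
  figures.

## The synthetic-data generator

No consortium files ship with the package; `simulate_two_sample()`
produces summary statistics with known ground truth instead.  Per SNP
$j$: $\gamma_j \sim U(0.08, 0.20)$ (positive by convention — sign
variation enters through allele coding, which keeps the truth
bookkeeping clean); a direct effect $\alpha_j$ that is 0 (`none`),
$N(0,\tau^2)$ (`balanced`, default $\tau = 0.01$) or $N(\mu,\tau^2)$
(`directional`, default $\mu = 0.02$, $\tau = 0.005$), drawn
independently of $\gamma_j$ so InSIDE holds; observed
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$ with
$\sigma_X = 0.008$ (the scale of a meta-analysis of roughly 2×10⁵
samples) and
$\hat\beta_{Yj} \sim N(\beta\gamma_j + \alpha_j, \sigma_{Yj}^2)$ with
$\sigma_Y \sim U(0.01, 0.03)$.  With these defaults every observed
exposure z-score exceeds 10, so simulated instruments pass the
$5\times10^{-8}$ filter by construction.  A `frac_invalid` field
restricts the direct effects to a leading subset of SNPs, which is how
the ">50% of weight valid" robustness of the weighted median is
exercised (40% invalid by count approximates 40% of weight here because
the weights are near-equal by construction).  Optional block LD
(consecutive blocks, constant within-block $r^2$) and allele-coding
corruption (swaps, strand flips, palindrome assignment) stress the
selection and harmonization stages; the truth record stores every draw
and corruption action, so tests can demand *exact* restoration.

One global seed is split into three independent streams — effects,
sampling noise, allele bookkeeping — so toggling corruption never
changes the effect draws.

What the generator does **not** emulate: realistic allele-frequency
spectra and frequency-dependent power, winner's curse in the discovery
GWAS, sample overlap between studies, non-normal effect distributions,
and LD beyond constant-$r^2$ blocks.  Passing tests therefore certify
the pipeline's algebra, bookkeeping, and frequentist calibration under
the stated generative model — not robustness to every pathology of real
consortium data.

## Numerical and degenerate-input behaviour

* `beta_x = 0` has no ratio estimate: a degenerate-instrument error.
* MR-Egger requires ≥ 3 instruments and at least two distinct
  $|\hat\beta_X|$ values; an exactly collinear input returns the exact
  fit with zero residual SD (p-values floored at the smallest positive
  double rather than returning 0).
* The weighted median at a bracketing boundary ($s_1 \ge 0.5$ or
  $s_m \le 0.5$) returns the boundary ratio; interior points
  interpolate linearly.
* Validation drops and logs; it never rewrites a value.  Empty results
  at any stage raise typed errors (`mrpipe_empty_input`,
  `mrpipe_empty_result`) that the grid runner converts into per-pair
  failure records without aborting other pairs.
* Bootstrap replication counts below 100 trigger a degraded-inference
  warning; the seed is a required argument, so no result depends on
  session RNG state.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated
data at the scale of the motivating analysis: 25–40 instruments per
exposure, 1,000 replicates for recovery/coverage/type-I-error
properties, 500 for the directional-pleiotropy intercept, 100-replicate
bootstraps inside simulation loops (1,000 by default for a single
analysis).  A full run of either finishes in about a minute on one CPU.

## Known limitations

* **Exposure measurement error.**  Wald ratios divide by the *observed*
  $\hat\beta_X$; with $\sigma_X = 0.008$ against exposure effects of
  0.08–0.20 this leaves a regression-dilution of about 5% of the slope
  in MR-Egger (the NOME/$I^2_{GX}$ issue), visible as a small positive
  offset (~0.001–0.002) in the mean Egger intercept under directional
  pleiotropy.  IVW is much less affected because dilution enters both
  numerator and weights symmetrically.
* **No heterogeneity statistics** (Cochran's Q, $I^2$), no MR-PRESSO,
  no multivariable MR, no leave-one-out scans: out of scope by design.
* **LD handling is pruning-only** (pairwise $r^2$ against kept
  instruments); no distance-window clumping, no reference-panel
  computation of LD — $r^2$ is an input.
* The weighted-median bootstrap treats the reported SEs as exact.

## A complete worked run

The 5-SNP deterministic fixture exercises every branch: one variant is
pruned ($r^2 = 0.2$ with a better instrument), one is absent from the
outcome study and replaced by a proxy ($r^2 = 0.9$), one needs an
allele swap, one a strand flip, and one palindromic variant is dropped.

```{r worked}
fx <- make_worked_fixture()
res <- mr_pair(fx$exposure, fx$outcome, ld = fx$ld, seed = 42)
format_results(res) |> dplyr::glimpse()
compare_estimators(res)
```

The same tables ship as TSV under `system.file("extdata", package =
"mrpipe")`, and `run_analysis()` executes the identical chain over an
exposure-by-outcome grid from a YAML configuration, writing the results
table, its JSON mirror, harmonization audits and a run log.
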