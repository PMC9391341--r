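---
title: "Reconstructing radiation dose from blood gene-expression signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing radiation dose from blood gene-expression signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsig)
```

## The problem

After an accidental or malicious radiation exposure, the absorbed dose of an
individual must be estimated from biology, because nobody wears a dosimeter.
Gene expression in peripheral blood is a sensitive and field-deployable
endpoint for this: a set of transcripts rises with dose (p53-driven DNA
damage response genes such as *Phlda3*, *Aen*, *Bax*) and another set falls
(markers of radiosensitive lymphocyte populations such as *Cd19*, *Cxcr5*,
*Ly6D*, *Ccr7*). `radsig` implements a complete, testable version of the
mouse-blood workflow: signature discovery on merged public microarray
studies, dimension reduction to a scalar *net signal*, robust
dose-reconstruction modelling with a time term, resampling validation, and
an independent qRT-PCR calibration with a sex-effect screen.

## The net signal

Individual dose-responsive genes are strongly correlated with one another,
so they are not treated as independent predictors. Instead a signature of
$n_{up}$ up-regulated and $n_{down}$ down-regulated genes (default 20 and
10 for arrays) is collapsed per sample to

$$N = \operatorname{agg}_{g \in up}(x_g) - \operatorname{agg}_{g \in down}(x_g),$$

where $x_g$ is the log-scale signal (arrays) or $\Delta C_t$ (qPCR) and the
aggregate is the median (arrays) or the geometric mean (qPCR; on the
log$_2$-scale $\Delta C_t$ values this is the arithmetic mean). Two exact
invariances make $N$ robust in practice and are asserted in the test suite:
any additive per-sample constant (array scaling, loading differences)
cancels, and swapping the two groups negates $N$.

Sign convention: on arrays, up-gene signal rises with dose, so $N$
increases with dose. In qPCR, more template means a *lower* cycle
threshold, so up-gene $\Delta C_t$ falls and $N = \text{agg(up)} -
\text{agg(down)}$ *decreases* with dose — hence the negative linear
coefficient in the qPCR calibration below.

## Dose-reconstruction models

**Microarray model.** Dose is regressed directly on the net signal and the
time after exposure $T$ (days):

$$D = k_1 N + k_2 N^2 + k_3 \sqrt{T},$$

with no intercept, so that $D = 0$ at $N = 0,\ T = 0$. Although the model
is nonlinear in $(N, T)$, it is linear in $(k_1, k_2, k_3)$ given the
regressors $(N, N^2, \sqrt T)$, so the OLS variant has a closed-form
solution, which doubles as an oracle check for the default robust fit. The
robust loss is Tukey bisquare M-estimation: iteratively reweighted least
squares with tuning constant $c = 4.685$ (95% Gaussian efficiency), scale
$\hat\sigma = \operatorname{median}|r| / 0.6745$ re-estimated every
iteration, at most 50 iterations, convergence when the largest coefficient
change falls below $10^{-8}$. When a fit is exact the scale collapses; the
implementation then returns the OLS solution with unit weights, which is
also the mathematical limit. Standard errors come from the final weighted
linear system and p-values from the $t$ distribution on the residual
degrees of freedom. `compare_time_structures()` fits the six structural
variants (time term $\sqrt T$, $T$ or $T^2$; additive or multiplying the
dose-response polynomial) under both losses and ranks them by mean test
RMSE over repeated half splits.

**qPCR calibration.** For the validation cohort, dose is regressed on
$\{1, N, N^2, \mathrm{Sex}, \mathrm{Sex}{\times}N, \mathrm{Sex}{\times}N^2\}$
(male = 1, female = 0). If no sex-containing term reaches $p \le \alpha$
(default 0.05), `reduce_model()` refits the reduced calibration
$D = b_0 + b_1 N + b_2 N^2$; otherwise the full model is returned with a
flag. Reconstructed doses are reported both raw and floored at 0; all fit
metrics (RMSE, $R^2$) use the raw values, because flooring would make the
metric depend on a reporting convention.

## qPCR processing conventions

Replicate wells are combined by arithmetic mean, with pairs whose spread
exceeds 0.5 cycles flagged but never dropped (no automatic well QC).
Because the arithmetic mean commutes with the $\Delta C_t$ subtraction,
averaging wells before or after normalization is equivalent; the package
averages first. The normalizer is the mean Ct of the reference genes
(*Actb*, *Gapdh* by default), i.e. the geometric mean of their linear-scale
expression. Fold changes use $2^{-\Delta\Delta C_t}$ against the mean
$\Delta C_t$ of all dose-0 animals, both sexes pooled (the sex screen
justifies pooling).

## What the synthetic generators emulate

The generators invert the two dose models so that every downstream stage
has a known ground truth and parameter recovery is an exact test, not a
plausibility argument.

**Arrays** (`generate_array_study()`): for each sample at dose $D$ and time
$T$ the generative net signal $N^*$ solves
$k_1 N + k_2 N^2 = D - k_3\sqrt T$ (positive root). Where
$D < k_3 \sqrt T$ — low doses at late times, including all controls —
$N^*$ is floored at 0, since dose 0 defines the baseline and the signature
cannot go below it. Up/down signature genes sit at
$\text{baseline}_g \pm w_g N^*/2$ plus a per-study batch offset and
Gaussian log$_2$ noise; background genes have no dose term. The default
per-gene weights are 1, so the difference of group medians reproduces
$N^*$ exactly; per-gene baselines are drawn once per study from
$\mathcal N(\mu = 8, \sigma = 1.5)$, typical of normalized log$_2$
intensities.

Two consequences are worth stating plainly. First, the floor means the
no-intercept model is misspecified for floored samples (the model predicts
$k_3\sqrt T$ there, the true dose is lower), so coefficient recovery on the
full dose range is approximate — exactly as dose reconstruction on real
low-dose, late-time samples is hardest. The exact round-trip checks
therefore use conditions on the invertible region (doses ≥ 1 Gy at ≤ 1
day). Second, because the up- and down-group baseline medians do not cancel
exactly in any finite random draw, the realized net signal carries a
dataset-specific additive offset; with a no-intercept model this propagates
into seed-to-seed variation of the fitted $k$'s. Both effects are
properties of the median-difference statistic itself, not artifacts.

**qPCR** (`generate_qpcr_cohort()`): the generative $N^*(D)$ is the
decreasing-branch root of $b_2 N^2 + b_1 N + (b_0 - D) = 0$; per-gene
target $\Delta C_t$ values are $\text{offset}_g \pm N^*/2$, with the
default offsets chosen with equal up/down group means so that the group
mean difference equals $N^*$ by construction. Raw Ct adds the reference
baseline (Ct 19/21 for *Actb*/*Gapdh*), a per-mouse loading shift
($\sigma = 0.3$ cycles, cancelled by normalization, present to exercise
that invariance) and per-well noise ($\sigma = 0.2$ cycles, a typical
TaqMan duplicate spread). An optional `sex_effect` shifts male net signals;
its default of 0 encodes the observed absence of sex differences.

**What the generators do not emulate:** probe-level array artifacts,
normalization failures, amplification-efficiency differences between
assays, inter-animal biological variability beyond the technical noise
term, and genes whose dose response saturates or is non-monotone. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated generative model, not performance on real cohorts; on real data
the reconstruction error is dominated by exactly the biology the generator
idealizes away, so synthetic RMSE values are optimistic.

## Default study conditions and sizes

| Parameter | Default | Why |
|---|---|---|
| array doses | 0, 1, 2, 4, 6, 8, 10 Gy | range of the merged public studies |
| array times | 0.25–7 days | early-to-late sampling window |
| array genes | 20 up + 10 down + 470 background | signature sizes used for arrays |
| $(k_1, k_2, k_3)$ | 0.906 Gy$^{-1}$, 0.274 Gy$^{-2}$, 0.549 d$^{-1/2}$ | fitted microarray calibration |
| array noise | 0.5 log$_2$ units | moderate inter-sample scatter |
| qPCR cohort | 5/sex/dose at 0, 1, 2, 3, 4, 6, 8 Gy, 24 h | validation cohort design |
| $(b_0, b_1, b_2)$ | 2.592, −0.785, 0.048 | fitted qPCR calibration |
| qPCR signature | up: *Phlda3*, *Rhoc*, *Lrg1*; down: *Cd19*, *Cxcr5*, *Ly6D*, *Ccr7* | final 7-gene panel |
| splits | 1000 random halves | stability assessment |

Statistical checks in the test suite run at reduced but still informative
sizes chosen for sharp expectations at small cost: 200 seeds for parameter
recovery (300 array samples / 70 mice each), 100 seeds for the sex-null
screen, 200 half splits for the resampling properties.

## Numerical and design choices

- **Spearman p-values**: large-sample $t$ approximation for $n \ge 10$;
  for smaller untied samples the exact permutation-null distribution.
  Ties at small $n$ fall back to the approximation. The Bonferroni
  multiplier is the number of genes actually tested; constant genes are
  flagged and excluded from both ranking and the multiplier.
- **Tie-breaks in signature selection**: equal correlations are ordered by
  smaller raw p-value, then gene ID, making selection fully deterministic.
- **Half splits**: per-split seed = base seed + split index, so a full
  1000-split run reproduces from one integer. The default split is
  unstratified; a dose-stratified mode keeps small dose groups in both
  halves (odd strata alternate their leftover sample between halves).
- **Degenerate inputs**: a single time point makes the time-structure
  comparison unidentifiable — all variants are reported as tied rather
  than ranked on noise. An all-zero fit (no dose, no signal) returns a
  zero time coefficient with aliased polynomial terms reported as `NA`.
- **Flooring**: negative reconstructed doses are physically impossible but
  statistically informative; both the raw and the floored value are always
  returned, and metrics use raw ones.

## Limitations

The package deliberately stops at pre-normalized inputs: no probe
collapsing, no cross-platform matching, no renormalization of public
datasets. The sex screen is a fixed-level coefficient test, not model
selection by information criterion. Dose reconstruction is a direct
regression of dose on signal, matching the source workflow, not an inverse
(calibration-curve) estimator with uncertainty propagation.
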