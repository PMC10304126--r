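---
title: "Models and methods for multi-environment trial stability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for multi-environment trial stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
```

## The data model

`metstab` analyses *balanced* multi-environment trials (METs): g genotypes
grown in e environments (location–year combinations), each trial laid out
as a randomized complete block design (RCBD) with r blocks. The plot model
is

$$y_{ger} = \mu + \alpha_g + \beta_e + (\alpha\beta)_{ge} + b_{er} +
\varepsilon_{ger},$$

with genotype effects $\alpha_g$, environment effects $\beta_e$, the
genotype-by-environment interaction $(\alpha\beta)_{ge}$, blocks nested in
environments $b_{er}$, and plot error $\varepsilon$. Block labels are
**local to an environment**: block "1" in one trial has no connection to
block "1" in another, and balance is therefore judged per trial. Missing
cells are a hard error for model fitting; `subset_balanced()` extracts a
complete sub-block, which mirrors how balanced analysis sets are carved
out of multi-year breeding archives. No imputation is attempted — imputed
cells would silently distort every SVD-based quantity downstream.

## ANOVA, shares and the signal/noise partition

`joint_anova()` partitions the plot sum of squares into ENV (df $e-1$),
REP(ENV) (df $e(r-1)$), GEN (df $g-1$), GEN:ENV (df $(g-1)(e-1)$) and
residual (df $e(g-1)(r-1)$), testing genotype terms against the residual
and environments against blocks. The reported *shares* are each factor's
fraction of $SS_G + SS_E + SS_{GE}$ — blocks and residual excluded — which
is the conventional headline figure for how environment-driven a trial
archive is.

Because $E[SS_{GE}]$ contains $df_{GE}\,\sigma^2$ even with no real
interaction, the interaction is split into a noise part
$SS_{noise} = df_{GE} \cdot MS_{res}$ and a signal part
$SS_{signal} = SS_{GE} - SS_{noise}$ (clamped at zero). The signal
fraction is the share of interaction worth modelling with multiplicative
axes; values near zero argue for a purely additive model.

## AMMI

`fit_ammi()` works on the $g \times e$ table of cell means: main effects
from row/column means, then the SVD of the doubly-centered residual
$Z_{ge} = \bar y_{ge} - \bar y_{g\cdot} - \bar y_{\cdot e} +
\bar y_{\cdot\cdot}$. The SVD is computed on the means basis; axis sums of
squares are converted to the plot basis as $r\lambda_k^2$ for F-tests, the
layout conventional for RCBD-replicated AMMI ANOVA. Axis F-tests use
Gollob degrees of freedom $g + e - 1 - 2k$ against the plot residual mean
square. The Gollob test is the dominant convention and is simple and
deterministic, but it is known to be liberal: axes beyond the true
structural rank can reach nominal significance, which is exactly why the
signal/noise partition and cross-validation are offered alongside the
postdictive tests.

Numerical conventions: singular values are kept in the nonincreasing order
returned by the decomposition; ties are left in that stable order; the
sign of each axis pair is fixed by making the largest-magnitude genotype
loading positive, so scores reproduce across platforms. A rank-0 centered
matrix is a valid fit with all $\lambda_k = 0$.

## Variance components and BLUP

`variance_components()` uses the closed-form expected-mean-square
(moment) estimators for the balanced two-way layout:
$\hat\sigma^2_{res} = MS_{res}$,
$\hat\sigma^2_{ge} = (MS_{GE} - MS_{res})/r$,
$\hat\sigma^2_{g} = (MS_G - MS_{GE})/(er)$, truncated at zero *before*
any shrinkage weight is formed, so weights stay in $[0,1]$. On balanced
data these coincide with REML away from the truncation boundary (the test
suite checks this against an independent REML fit) while remaining exactly
testable. Genotypes and their interaction are treated as random;
environments and blocks enter as fixed centering and are not predicted —
the construction under which the WAASB index is defined.

`genotype_blups()` shrinks raw genotype means with
$w = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/e + \sigma^2_{res}/(er))$;
on balanced data the weight is common, so the ranking equals the raw-mean
ranking and the value added is the shrinkage magnitude (and honest
prediction in cross-validation). `blup_ge_matrix()` shrinks the centered
interaction residual by $s = \sigma^2_{ge}/(\sigma^2_{ge} +
\sigma^2_{res}/r)$, discounting the part of the observed interaction that
is plot noise.

## WAASB and quadrants

The WAASB index of entity i (genotype or environment) is the weighted
average of its absolute scores over *all* $p = \min(g-1, e-1)$ axes of the
SVD of the BLUP GE matrix, weighted by the variance explained per axis.
All axes are used because the defining formula sums to p without
qualification. Scores use symmetric scaling (singular vector times
$\sqrt\lambda$) so genotypes and environments share one biplot scale; the
scaling choice does not affect which entities are relatively stable under
a fixed axis weighting, and it is the one setting under which the joint
genotype/environment display is natural.

Quadrants of the WAASB-by-yield plot use cut-offs at the mean yield and
mean WAASB of the classified entities (the crosshair convention of the
standard plot). Ties are resolved deterministically: yield at the cut-off
counts as "high", WAASB at the cut-off as "stable", so an entity exactly
on both lines is quadrant IV. `waasby()` blends rescaled performance
(max yield → 100) and stability (min WAASB → 100) with a user weight;
constant input vectors cannot be rescaled and are an error rather than a
silent division by zero.

## GGE ranking

`fit_gge()` centers the mean table by environment means (retaining G+GE),
applies no scaling, and uses genotype-focused singular-value partitioning
— the conventional settings for genotype-ranking biplots. The ideal
genotype sits on the average-environment direction at the largest genotype
projection; genotypes are ranked by two-axis Euclidean distance to it. Two
axes are always used for the ranking geometry (matching the printed 2-D
displays); with a single environment the geometry collapses to one axis
and the ranking reduces to the mean-yield ranking.

## Cross-validation

`cv_compare()` splits each environment's blocks into training (r−1) and
validation (1) sets, drawing the held-out block uniformly per environment.
All AMMI members are fitted to the training cell means; BLUP predictions
for a validation cell are $\hat\mu + w(\bar y_{g\cdot} - \hat\mu) +
(\bar y_{\cdot e} - \hat\mu) + s\,z_{ge}$, i.e. cell-level predictions,
with variance components re-estimated inside every training resample —
honest cross-validation, since the resample is supposed to know nothing
about the held-out block. Models are scored by RMSPD over validation
plots. Among AMMI members of comparable accuracy (mean RMSPD within a
configurable 1% of the best), the smallest k is reported as chosen,
making the usual "prefer the simpler model" advice operational.

## Weather covariates and PLSR

`aggregate_weather()` cuts each month into days 1–10, 11–20 and 21 to
month end, averaging maximum temperature and totalling rainfall per
period, and counts rainless days and hot days (threshold inclusive,
default 90 on the Fahrenheit scale — the physically meaningful reading of
a hot-day threshold for temperate growing regions; the value is a
parameter) for June and July. August covariates can be requested but are
excluded from the default variable set, matching the usual May–July
screening window for spring-sown pulses. Pearson screening is
pairwise-complete; zero-variance columns report `NA`.

`plsr_fit()` is a univariate-response NIPALS: covariates autoscaled,
response centered, coefficients reported on the standardized-predictor
scale so signs and relative magnitudes read directly as effect directions.
With as many components as the predictor rank it reproduces ordinary least
squares (a test asserts this); the default of two components is the usual
choice for a coefficient screen with few environments and many collinear
covariates, and is configurable. The suite cross-checks predictions
against an independent PLS implementation.

## The synthetic generator

`generate_met()` draws every term of the plot model with known values:
centered Gaussian genotype, environment and block effects; a planted
multiplicative interaction with prescribed singular values on orthonormal
(centered) axes; optionally an unstructured iid Gaussian interaction; and
Gaussian plot error. A designated genotype can be given a zero interaction
row — a perfectly stable entry — and a fixed main-effect vector can be
supplied, which is how the quadrant-IV recovery tests plant their known
answer.

The `pea_like` preset (g = 12, e = 28, r = 3, $\mu$ = 2.7 t/ha) encodes
the regime of a year-driven temperate yield-trial archive:
$\sigma^2_e = 0.884$, $\sigma^2_g = 0.031$, $\sigma^2_b = 0.01$,
$\sigma^2_{res} = 0.09$ (a trial CV of about 11% at a 2.7 t/ha mean),
giving expected G/E/GE shares of about 0.03/0.90/0.07. The interaction
mixes two strong planted axes ($\lambda$ = 2.005, 1.418, about 45% of the
expected interaction signal) with a diffuse full-rank Gaussian tail
($\sigma^2_{ge}$ = 0.0248, the remaining 55%), for an expected signal
fraction near 0.6. The mixed structure is deliberate: archives of real
trials show several nominally significant axes with only one to three
carrying most of the signal, i.e. the interaction is not exactly low-rank.
Under a purely rank-2 interaction, truncating at the true rank would
dominate uniform BLUP shrinkage by construction, and the cross-validation
comparison would say nothing about data of realistic structure.

What the generator does *not* emulate: heteroscedastic trial errors,
non-Gaussian plots, spatial trend within trials, unbalanced or augmented
designs, and genetic relatedness among entries. Passing recovery tests on
these simulations therefore demonstrates correctness of the estimators
under the stated model, not robustness to those violations.

`generate_weather_yield()` simulates daily May–August weather with
environment-level warmth and dryness offsets, then builds environment mean
yields as a linear function of chosen standardized covariates plus noise,
so correlation/PLSR sign-recovery is testable with a known answer.

## Problem sizes and reproducibility

All stochastic procedures take explicit integer seeds and are
deterministic given them. The shipped checks use 200 cross-validation
resamples (mean RMSPDs are stable to well under the observed
between-model margins at that depth), 200 replicates for
variance-component recovery, and 25–30 seeds for the axis-significance and
quadrant-recovery frequencies; these sizes were chosen so the complete
suite exercises every claim at meaningful precision while staying quick to
run. The classical choice of 1000 resamples remains the default of
`cv_compare()` for applied use.

## Known limitations

- Only balanced data are modelled; there is no imputation-based AMMI and
  no weighted or robust variant.
- Variance components are moment estimators; heterogeneous per-environment
  error variances and pedigree/kinship information are out of scope.
- The Gollob axis test is approximate and liberal; use the signal fraction
  and cross-validation for model choice, as the model-assessment functions
  encourage.
- Quadrant cut-offs follow the crosshair (grand-mean) convention; other
  published displays draw cut-offs at different anchors, so labels are
  comparable only under the same convention.
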