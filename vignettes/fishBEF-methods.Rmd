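---
title: "Process-based biodiversity–ecosystem function analysis for reef fishes"
author: "fishBEF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process-based biodiversity–ecosystem function analysis for reef fishes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fishBEF)
```

## Overview

fishBEF links biodiversity to a process-based measure of ecosystem
function — the biomass a reef fish community accrues through one day of
somatic growth — and asks how that link changes as the definition of
"diversity" moves along the evenness–rarity continuum. This vignette is
the package's methodological account: the models, the assumptions behind
them, the tunable parameters and their defaults, what the synthetic-data
generators do and do not emulate, and the numerical choices that a user
extending the package should know about.

## Standardized growth: K_max

Published fish growth studies report von Bertalanffy parameters
$(L_\infty, K)$ for $L(t) = L_\infty(1 - e^{-K(t - t_0)})$. $K$ values are
not comparable across studies because each is tied to its own asymptote.
We therefore re-express every fit as $K_{\max}$: the growth coefficient
the same trajectory implies when its asymptote is set to the species'
maximum recorded total length $L_{\max}$.

`computeKmax()` finds the $K'$ minimizing

$$\sum_{j=1}^{100}\left[L_{\max}(1 - e^{-K' t_j}) -
  L_\infty(1 - e^{-K t_j})\right]^2$$

over 100 equally spaced ages on $[0, t_{95}]$, where $t_{95}$ is the age
at 95% of $L_\infty$. Properties that the test suite verifies: when
$L_\infty = L_{\max}$, $K_{\max} = K$ exactly; rescaling both lengths by a
common factor leaves $K_{\max}$ unchanged; and the optimizer agrees with a
brute-force grid search at $10^{-4}$ resolution. Two deliberate choices:

* $t_0$ is fixed at 0 throughout. $K_{\max}$ concerns trajectory *shape*;
  letting $t_0$ float would introduce an offset that published parameter
  pairs cannot identify.
* The least-squares matching window $[0, t_{95}]$ weights the rising part
  of the curve and its plateau together. Matching on a different window
  (or matching initial slopes, which gives $K L_\infty / L_{\max}$) is a
  different standardization; the definition is isolated behind
  `computeKmax()` so an alternative can be swapped in.

Length standardization to total length uses per-species linear
length–length factors (`standardizeLength()`); a missing factor is an
error, never a silent pass-through. Record filtering
(`filterGrowthRecords()`) drops non-marine records, records without
coordinates, and exact (species, $L_\infty$, $K$, source) duplicates,
logging counts per reason.

## Trait-based prediction of K_max

Six predictors carry the growth signal: maximum body size (cm TL),
trophic level, maximum depth (m), water-column position, sea-surface
temperature (°C), and the aging method behind each growth curve (a known
source of systematic bias in growth estimates). Numeric traits missing at
the species level fall back to genus then family means, with the fallback
level recorded per row (`assembleFeatures()`).

Boosted regression trees are fitted under a gamma deviance loss
(`xgboost`, objective `reg:gamma`), matching the strictly positive,
right-skewed distribution of growth coefficients. Hyperparameters are
tuned in two steps on a validation fifth of the 80% build split: a coarse
random grid over the learning rate (0.1–0.9), the regularising gamma
(0.1–0.9), tree depth (5, 10, 15) and subsample rate (0.1–0.9), then a
local refinement around the step-1 optimum (±0.08 on continuous axes).
Both grids and their losses are kept in the fitted object. Holdout
performance on the untouched 20% is summarized as bias
(mean of predicted − observed) and the $R^2$ of the log–log least-squares
line (`evaluateHoldout()`).

Prediction uncertainty comes from bootstrapping the whole process: each of
`n_boot` iterations resamples the modelling table with replacement,
re-splits 80/20, refits at hyperparameters drawn from the step-2
neighbourhood of a reference fit, and predicts the targets. Re-tuning is
restricted to that neighbourhood because a full two-step search inside
every bootstrap would multiply the cost roughly twentyfold while the
winning region is stable across resamples. The 5%/50%/95% quantiles per
target form the 90% predicted quantile range. Predictions are floored at
$10^{-4}\,\mathrm{yr}^{-1}$. The package default is `n_boot = 1000`; the
worked examples and tests use 10–200, which the repeat-run comparisons in
the test suite show is already stable to Monte-Carlo error at the
tolerances used there.

## Daily biomass production

Productivity is expected biomass tomorrow minus observed biomass today,
summed over every censused individual, with no mortality applied — a
gross, growth-only flux over the 500 m² transect (two 250 m² blocks).
For one individual:

1. draw $K_{\max} \sim \mathcal N(m, s)$ truncated to $[q_{05}, q_{95}]$,
   with $m$ the interval midpoint and $s = (q_{95}-q_{05})/3.2897$, so the
   *untruncated* 90% interval equals the predicted quantile range (the
   draw itself is exact inverse-CDF sampling);
2. invert the VBGF at the individual's length (the size-class midpoint)
   with asymptote $L_{\max}$ and coefficient $K_{\max}$ to get its age;
3. advance $\Delta t = 1/365$ yr and convert with $W = aL^b$.

Individuals recorded at or above their species' asymptote cannot be aged;
they are placed at 99% of the asymptote for inversion, and because their
projected length then falls below their observed length, they contribute
zero production — consistent with growth vanishing at the asymptote.
Surveys with a single censused block are excluded (with a logged reason)
rather than scaled up, since block-level detection differences make
doubling a single block biased. Per-survey random streams are derived from
(global seed, survey id), so results are independent of survey ordering
and parallelizable. The vectorized implementation is tested against an
independent per-individual loop sharing the same uniform stream, to
$10^{-9}$.

## Hill diversity

$$D = \left(\sum_{i=1}^S p_i\,(1/p_i)^{\ell}\right)^{1/\ell},$$

with the $\ell \to 0$ limit $D = \exp(-\sum p_i \log p_i)$ used inside a
window of $10^{-8}$ around zero. $\ell = -1$ gives inverse Simpson,
$\ell = 0$ exponentiated Shannon, $\ell = 1$ richness, and $\ell = 10$ the
strongest rarity emphasis scanned — because a rare species can have at
most one individual less than any other, emphasising rarity de facto
emphasises communities with high total abundance. Evaluation is in
log-space (log-sum-exp of $(1-\ell)\log p_i$): at $\ell = 10$ the formula
raises rare-species $p_i^{-9}$, which overflows double precision in large
communities if evaluated directly.

Model inputs are natural-log diversity values (`diversityMatrix()`), which
tempers the leverage of hyperdiverse surveys; displays use the original
scale. The metric correlation structure is summarized by a PCA on
centered, unit-scaled columns (`pcaDiversity()`); correlation scaling is
used because the four log-diversity metrics have different variances and
the question is their correlation, not their scale. PC1 loadings are
sign-fixed positive when all pairwise correlations are positive.

## Hierarchical BEF models

Three responses share one linear predictor on the log scale:

$$\log \mu_i = \beta_0 + \beta_D \log x_D + \beta_{trop}\,x_{trop} +
  \beta_{D \times trop} \log x_D\, x_{trop} +
  \beta_{sst,vis,depth}\mathbf X_i + \alpha_{site},$$
$$\alpha_{site} = \alpha_{realm} + \varepsilon_{site},\qquad
  \varepsilon_{site} \sim \mathcal N(0, \sigma_{site}),\quad
  \alpha_{realm} \sim \mathcal N(0, \sigma_{realm}).$$

Total productivity is gamma with shape $\phi$ (variance $\mu^2/\phi$);
abundance is negative binomial with inverse shape $\omega$ (variance
$\mu + \mu^2/\omega$); per-capita productivity reuses the gamma model with
a log-abundance offset, which measures the per-individual rate while
keeping the error structure of the total. Priors: $\mathcal N(0,5)$ on the
intercept, $\mathcal N(0,1)$ on slopes, half-$\mathcal N(0,1)$ on both
random-effect scales (the realm-level prior is a package choice — only the
site level is pinned down by the model statement), and
$\mathrm{Gamma}(0.01, 0.01)$ on the shape. All continuous covariates are
z-scored (log diversity is logged first, then z-scored — the scaling rule
covers *all* continuous fixed effects); means and sds are stored for
back-transformation. SST can instead enter as Boltzmann inverse
temperature $1/(k_B T_K)$, $k_B = 8.617333\times10^{-5}$ eV K$^{-1}$,
before z-scoring.

### Sampler

Posteriors are drawn by the package's adaptive Hamiltonian Monte Carlo on
an unconstrained parameterization: random effects are non-centered
($\alpha = \sigma z$, $z \sim \mathcal N(0,1)$), scales and shapes are
log-transformed with Jacobians. Warmup follows the windowed scheme of
modern gradient-based samplers: a step-size-only opening phase, doubling
windows that re-estimate a diagonal mass matrix (each followed by a
dual-averaging restart), and a closing step-size phase. Step size targets
a 0.9 acceptance rate; trajectory lengths are a fixed integration time
(default 1.2) with ±30% jitter, capped at 64 leapfrog steps. The
likelihood/gradient kernel is compiled (Rcpp), with the gradient verified
against numerical differentiation in the tests, and the whole sampler
cross-checked against an independent Gibbs implementation (JAGS) of the
same model. The gamma shape is initialized from a method-of-moments
estimate of residual log-variance, which matters for near-deterministic
responses whose shape posterior sits orders of magnitude above a generic
starting point. Defaults are 4 chains, 2000 warmup, 4000 post-warmup
draws per chain ("sampling" counts post-warmup draws; the configurable
split is stored in the fit).

Non-finite log-posteriors or Hamiltonian divergences after warmup are
counted as divergent transitions. A fit with split-Rhat above 1.1 or more
than 5% divergences errors by default; `strict = FALSE` downgrades this to
a warning, which replicated simulation studies use because occasional
borderline replicates are expected and are handled by the aggregate
criteria. `checkConvergence()` reports split-Rhat and rank-normalized
bulk/tail ESS per parameter, with a pass flag at Rhat < 1.01 and a
reference ESS threshold of 1800.

Two model features mix slowest: the intercept trades off against the mean
of the (few) realm effects, and near-zero random-effect scales create a
funnel. The non-centered parameterization and the mass matrix handle both
well enough for the regression slopes, whose effective sample sizes are
typically several-fold higher than the intercept's.

### Model comparison and diagnostics

`psisLoo()` implements Pareto-smoothed importance-sampling leave-one-out
cross-validation from the pointwise log-likelihood matrix: raw weights
$1/p(y_i \mid \theta_s)$, generalized Pareto fit (empirical-Bayes
estimator with the weak shape prior) to the top
$\min(0.2S, 3\sqrt S)$ weights, replacement by expected order statistics
capped at the maximum, and the Pareto $\hat k$ diagnostic per observation
(warnings above 0.7). `compareModelsLoo()` ranks fits of the same
observations by LOOIC $= -2\,\widehat{\mathrm{elpd}}$.

`residualDiagnostics()` computes randomized-quantile (PIT) residuals from
posterior predictive draws — randomized within ties for the discrete
negative-binomial case — a Kolmogorov–Smirnov uniformity test, and a
Moran's I permutation test (999 permutations) on the normal-score
residuals with row-standardized inverse great-circle-distance weights;
coincident points get half the smallest positive distance, and fully
coincident coordinates skip the test with a warning. Two calibration
caveats verified in the tests: with a single observation per site the
posterior predictive partially fits each observation and PIT values become
under-dispersed, and observations sharing a site genuinely correlate
through the posterior of their site effect, so the spatial-independence
null is a statement about independent values at distinct locations, not
about within-site replicates.

## The synthetic world

The generators emulate the three inputs of the analysis with controllable
effect sizes and known ground truth (`synthConfig()` collects every knob):

* **Species pool** — maximum length log-normal (median 30 cm, log-sd 0.7),
  trophic level uniform 2.0–4.6, maximum depth log-normal, categorical
  water position; length–weight $a \in [0.005, 0.05]$,
  $b \in [2.8, 3.2]$. The latent growth link
  $\log K_{\max} = \log 0.5 - 0.6 \log(L_{\max}/30) + 0.3\,(SST-20)/10$
  falls with body size and rises with temperature, the two dominant
  gradients in fish growth.
* **Growth records** — per species, study locations with
  latitude-dependent SST, $K$ = latent mean × log-normal noise (log-sd
  0.2), $L_\infty$ uniform on $[0.7, 1.1] \times L_{\max}$, aging methods
  over six categories, and reported lengths in TL/SL/FL with the matching
  conversion table. Scale mirrors a mined database of several growth
  curves per species.
* **Surveys** — sites nested in four realms (two tropical at 24–29 °C,
  two temperate at 8–18 °C), each site holding a species pool of varying
  size (5–40) with a geometric-series abundance skew; pool size and skew
  jointly induce realistic covariation of richness, evenness and
  abundance. Counts are negative binomial around the configured abundance
  model driven by the site's latent (rarity-weighted) log diversity;
  individuals fall into census-style size bins (2.5–50 cm, then 12.5 cm
  steps — the bin scheme is a stand-in, as census programs differ) no
  larger than the species maximum, split binomially between two blocks.
  Default generating coefficients: abundance $\beta_D = 1.5$,
  $\omega = 2$; productivity $\beta_D = 1.10$, $\phi = 5$; both with
  $\sigma_{site} = 0.3$, $\sigma_{realm} = 0.4$ and weak environmental
  slopes.
* **Exact model-ready datasets** (`genGlmmExactDataset()`) draw responses
  *exactly* from the gamma or negative-binomial hierarchy with covariates
  z-scored inside the generated sample, so that recovery studies test the
  sampler, not the covariate bookkeeping.

Every generator derives an independent sub-seed from the one global seed,
so modules stay reproducible independently; seeded reruns are
bit-identical.

What the synthetic world does **not** emulate: detection and
identification error, species' geographic range structure (coordinates
exist only to exercise the spatial diagnostics), temporal revisits,
length–weight uncertainty, and the species-level dependence structure of
real survey counts (the abundance model is specified at the survey level;
species counts share it through the composition). A pipeline that passes
on these data is therefore validated for its computational and inferential
correctness — recovering what generated the data — not for robustness to
observational artefacts of real census programs.

## Problem sizes

The test suite and worked examples use deliberately reduced sizes chosen
to exercise every code path while staying comfortable on a laptop: surveys
in the dozens, bootstraps 10–200, chains 2 × (400–1000 warmup /
400–1000 draws), and a 50-replicate recovery study at $n = 400$ surveys.
The package defaults (`n_boot = 1000`; 4 chains, 2000/4000) are the
full-scale settings, restored in one step by
`runPipeline(..., full_scale = TRUE)`.

## Known limitations

* $K_{\max}$ depends on the matching-window convention (above); published
  standardizations differ in detail.
* The bootstrap prediction interval reflects resampling and refit
  variability around one tuning neighbourhood; a full re-tune per
  iteration could widen it slightly.
* Static-trajectory HMC with a diagonal mass matrix mixes the intercept
  and near-zero variance components more slowly than a dense-metric or
  dynamic-length sampler would; for the regression slopes this costs
  effective samples, not correctness, and the diagnostics make it visible.
* LOOIC comparisons inherit the usual caveat that pointwise predictive
  scores on clustered data treat observations, not sites, as the exchange
  unit.
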