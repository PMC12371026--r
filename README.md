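# fishBEF

Tools for asking how biodiversity relates to ecosystem function in marine
reef fish communities, using a *process-based* measure of function: the
biomass a community accrues through one day of somatic growth. The package
implements the full analysis chain — standardizing published growth curves,
predicting growth from traits, simulating daily biomass production for
every censused individual, quantifying diversity with Hill numbers, and
fitting hierarchical Bayesian models of the biodiversity–ecosystem
function (BEF) relationship — together with synthetic-data generators with
known ground truth so every stage can be validated end to end.

## The science in brief

**Standardized growth.** Published von Bertalanffy growth fits
L(t) = L∞(1 − e^(−K(t−t₀))) are re-expressed as **K_max**, the growth
coefficient the same trajectory implies when its asymptote is set to the
species' maximum recorded total length. K_max is found by least-squares
matching of the rescaled curve to the observed curve over 100 ages on
[0, t95] (`computeKmax()`).

**Trait-based prediction.** K_max is predicted from maximum body size,
trophic level, maximum depth, water-column position, sea-surface
temperature, and aging method with gradient-boosted trees under a gamma
loss, tuned in two steps (coarse random grid, then local refinement) on an
80/20 split, and bootstrapped to yield a 90% predicted quantile range per
species (`tuneAndFit()`, `bootstrapPredictIntervals()`).

**Productivity.** For every individual in a two-block 500 m² survey,
a K_max is drawn from a truncated normal over its species' predicted
quantile range, the individual is placed on its growth trajectory at its
size-class midpoint, advanced one day (Δt = 1/365 yr), and the length
increment converted to mass through W = aL^b. Summing over individuals and
repeating over bootstrap draws gives the survey's daily biomass production
with uncertainty (`communityProductivity()`).

**Diversity.** Hill diversity D = (Σ pᵢ (1/pᵢ)^ℓ)^(1/ℓ) spans the
evenness–rarity continuum through the scaling parameter ℓ: inverse Simpson
(ℓ = −1), exponentiated Shannon entropy (ℓ = 0, as the limit), species
richness (ℓ = 1), and abundance emphasis (ℓ = 10). `hillDiversity()`
evaluates the formula in log space so extreme ℓ cannot overflow.

**BEF models.** Productivity (gamma likelihood, shape φ), total abundance
(negative binomial, inverse shape ω), and per-capita productivity (gamma
with a log-abundance offset) are modelled on log Hill diversity with a
diversity × tropical interaction, z-scored environmental covariates (SST —
optionally as Boltzmann inverse temperature — visibility, depth), and
site-within-realm random intercepts. Posteriors are sampled with the
package's adaptive Hamiltonian Monte Carlo sampler (windowed warmup,
dual-averaging step size, diagonal mass matrix; the likelihood/gradient
kernel is in C++). Models across ℓ are ranked by PSIS-LOO
(`compareModelsLoo()`), and checked with split-Rhat/ESS diagnostics,
randomized-quantile residuals, and a Moran's I permutation test.

## Worked example

```r
library(fishBEF)

cfg <- synthConfig(n_species = 40, n_sites = 16, seed = 7)
res <- runPipeline(cfg, ell = c(-1, 0, 1, 10), n_boot = 20,
                   mcmc = list(chains = 2, warmup = 500, sampling = 500))

res$loo[, c("model", "ell", "looic", "delta_looic")]
#>                    model ell looic delta_looic
#> 4 productivity_abundance  10 306.6       0.000
#> 3  productivity_richness   1 315.0       8.428
#> 2   productivity_shannon   0 315.0       8.459
#> 1   productivity_simpson  -1 315.1       8.506

pipelineReport(res)$ell_scan[, c("ell", "b_D_median", "b_D_q05", "b_D_q95")]
#>   ell b_D_median b_D_q05 b_D_q95
#> 1  -1     -0.407 -0.9450   0.128
#> 2   0     -0.347 -0.9503   0.198
#> 3   1      0.079 -0.5590   0.810
#> 4  10      0.495 -0.0066   0.981
```

The abundance-emphasising scaling (ℓ = 10) gives the best-fitting BEF
model by LOOIC, and the ℓ-scan shows the slope turning from negative under
common-species weighting (ℓ = −1, 0) to clearly positive under abundance
weighting — the slopes are per standard deviation of log Hill diversity.
At this demo scale the intervals are wide; larger worlds sharpen the
pattern. `pipelineReport()` also tabulates posterior summaries for every
model, the LOOIC ranking, convergence diagnostics, and (for synthetic
worlds) a table comparing recovered abundance-model coefficients with the
generating ground truth.

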