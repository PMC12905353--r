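---
title: "Methods: empirical fire-regime modelling, scenario projection and driver attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: empirical fire-regime modelling, scenario projection and driver attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fireglm)
```

## The modelling problem

Wildfire regimes are described here by three grid-cell properties: monthly
mean burnt-area fraction (BA), monthly median fire size (FS, km²) and a
monthly median fire-intensity metric (FI, fire radiative power divided by the
square root of median fire size, W km⁻¹). Each is modelled as a generalised
linear function of sixteen gridded predictors covering climate, vegetation,
topography, human activity and ignitions (`predictor_info()` lists names,
units, factor groups and physical bounds). The approach is a space-for-time
substitution: spatial gradients in the training data stand in for temporal
change, which is what lets the fitted models be driven with end-of-century
forcings.

## The three GLMs and their assumptions

Burnt-area fraction is equated with the probability of burning, so `fit_fire_glm(..., "BA")`
fits a quasi-binomial model with a logit link; the free Pearson dispersion
absorbs over- or under-dispersion relative to the binomial variance
function. FS and FI are heavy-tailed with many very small values, and are
fitted as quasi-Poisson with a log link after min-max normalisation of the
response to [0, 1]. Design choices a user should know:

* **Standardisation.** Predictors are z-scored on the training sample and the
  constants persist inside the model, so coefficients are comparable across
  units and t-values (β/se) rank predictor importance. All downstream
  operations (prediction, attribution) reuse the training standardisation.
* **Main effects only.** The sixteen predictors enter linearly on the link
  scale, without interactions or transforms; whether the original global fits
  contained such terms is not recoverable, so the simplest defensible design
  was chosen.
* **Min-max normalisation** of FS/FI is global (one min and max over the whole
  training field, not per month) and its constants round-trip predictions to
  physical units exactly. The Pearson dispersion on the normalised scale
  relates to the physical scale by the factor (max − min) when the minimum is
  zero; `dispersion(model, scale = "response")` applies that rescaling, and a
  test verifies it against a direct quasi-Poisson fit on the raw counts.
* **Convergence.** IRLS (via `stats::glm`) with deviance tolerance 1e-8 and at
  most 100 iterations; non-convergence and rank deficiency are errors naming
  the problem, never silent.
* **Confidence intervals.** The 95% band is built as fitted ± 1.96·SE on the
  linear-predictor scale and back-transformed, which keeps BA intervals inside
  (0, 1). The source description of the interval rule can also be read
  literally as a multiplicative band on the response scale; that reading is
  available as `predictive_interval(..., method = "multiplicative")`.
* **Partial residuals** are working residuals plus βⱼzⱼ. Orthogonality of
  working residuals holds in the IRLS weighted metric, so the slope-recovery
  property (regressing partial residuals on zⱼ returns βⱼ) is exact under
  weighted, not ordinary, least squares; the returned frame carries the
  weights.

## Ignition threshold and the True Skill Statistic

The BA model is probabilistic and never predicts exactly zero, while FS and
FI models return a value even where burning is impossible. The gate is a
threshold on fitted BA, derived as a quantile — the median by default — of
fitted values in cells whose *observed* BA is zero (`derive_threshold()`).
Numerical choices: the quantile uses linear interpolation between order
statistics (R type 7, the common default; the source does not state one);
a cell is classified burnable when fitted BA ≥ threshold, and FS/FI are
zeroed where fitted BA < threshold — the two rules are complementary and
gating is idempotent. Skill is measured by TSS = sensitivity + specificity −
1, which is prevalence-independent; the reported `maxTSS` column equals
TSS + 1 identically, matching every row of the bundled reference table
(`reference_tss_table()`), and is carried as that identity.

## Vegetation inputs

Upstream vegetation processing is reduced to its algebra: fAPAR from LAI by
Beer–Lambert extinction, `1 − exp(−k·LAI)` with k = 0.5 (dimensionless
extinction coefficient); PPFD from shortwave radiation by
`86400 × 10⁻⁶ × kEC × rsds` with kEC = 2.04 µmol J⁻¹ (mol m⁻² day⁻¹ per
W m⁻²); monthly GPP as the convex combination
`GPP_C3·(1 − C4_frac) + GPP_C4·C4_frac`. As printed, the source's mixture
formula repeats the C3 term in both positions; the surrounding text defines
separate C3 and C4 components, so the second term uses GPP_C4 here — an
obvious typographical slip, flagged rather than silently absorbed. fAPAR
rescaling to an observational reference multiplies by the baseline-period
ratio and clips to [0, 1 − 1e-9], preserving the open interval so downstream
logarithms stay finite; cells with a zero baseline simulation but nonzero
reference cannot be rescaled and get ratio 1 with a warning. Cloud cover for
future periods comes from a least-squares line on paired baseline monthly
means of shortwave and cloudiness, predictions clipped to [0, 1]; fewer than
three pairs or a constant baseline is an error. GPP units are treated as
opaque "training units" throughout: the GLMs standardise predictors, so
absolute units cancel.

## Scenario construction

Future forcings use the anomaly (delta) method: the difference between a
GCM's future and piControl monthly climatologies is added to the observed
baseline climatology, so any bias shared by the two simulated states cancels.
Anomalies are additive for every variable (no multiplicative deltas); after
addition, clip rules restore physical ranges — dry days to [0, days-in-month],
VPD/DTR/wind/lightning to ≥ 0, fractions to [0, 1] — and a bounded variable
without a clip rule is an error. Clipping never moves a value already within
bounds. Monthly climatologies are then collapsed to the single-layer
predictors: dry days and lightning as annual means, dry-day seasonality as
(max − min)/mean per cell, VPD and DTR from the month with the largest
spatial-mean value, wind from the hottest month.

The factorial design crosses five experiments (realistic; climate only; CO₂
only; climate + CO₂; human only) with two RCPs and four GCM members — 40
experiments. Factor-group membership: climate covers the five climate layers
plus the climate response of vegetation; CO₂ covers the CO₂ response of
vegetation (GPP, GPP seasonality, covers); human covers population, cropland
and roads; ruggedness, topographic position and lightning are constant
everywhere. In the climate-only experiment vegetation responds to future
climate at modern CO₂ (held-constant factors are pinned at modern levels);
hold-outs are bit-identical to the baseline, and tests assert this. Road
density is projected from population density, GDP per capita, OECD membership
and cell area by least squares, predictions clamped at zero; GDP per capita
is total GDP over the population count, and zero-population cells take the
grid median (flagged) instead of dividing by zero.

## Attribution and aggregation

The change in a fire property between two experiments is decomposed per cell
as Δzⱼ·βⱼ on the (standardised) linear-predictor scale — the first-order,
additive term of a forcing decomposition. The per-predictor contributions sum
to the total linear-predictor change at machine precision, which the tests
assert exactly. Contributions live on the link scale because that is the only
scale on which Δx·β is meaningful; response-scale effects are reported
separately as predicted-property differences. Dominant drivers are the
largest positive and most negative contributions per cell; exact ties resolve
to the lowest-index predictor in the canonical layout, and zero contributions
never win. Burnt area aggregates to biomes as Σ(BA × cell area) with
spherical cell areas; global percentages use the sum over the aggregated rows
as denominator — also the convention under which every percentage in the
bundled reference biome table reproduces to two decimals (that table's
separately printed modern global total disagrees with its own row sum by
about 0.03%, and both numbers are retained). Change maps use relative change
with the modern value as denominator and a 5% minimum; modern-zero cells are
excluded rather than mapped to infinity. The tropics boundary defaults to
±23.5° latitude and is configurable.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` produces spatially autocorrelated predictor fields
(smoothed Gaussian noise, default correlation length 4 cells) with plausible
marginals and a land-cover simplex (tree + grass + shrub + bare = 1), then
draws fire observations from known coefficients. Burnt area takes a Beta
disturbance around the inverse-logit mean — mean-exact, supported on (0, 1),
with exactly the binomial variance shape — rather than truncated additive
noise, which would bias the mean near the bounds; the precision default (50)
keeps observation noise small relative to spatial signal. FS and FI are
gamma-mixed Poisson (negative-binomial) counts with variance = dispersion ×
mean, the standard generative family behind a quasi-Poisson fit; dispersion
defaults to 3. The zero-inflation mass is imposed by thresholding the latent
burning probability — the fire-free 26% of cells are those with the lowest
latent probability — so the ignition-threshold machinery sees the same
structure the observational analysis exploits, rather than an independent
Bernoulli mask.

The default ground truth is calibrated once from the observational anchors:
intercept −4.5 and slope vector with ‖β‖ ≈ 1.95 on z-scored predictors place
the median fitted BA of the fire-free cells near 1e-3 (the 13th percentile of
a logit-normal with those parameters is ≈ 0.0012), the zero share at 26%, and
mean burnt area at a few percent. What the generator does *not* emulate: real
GCM covariance structure, ocean/land geography, monthly fire seasonality, and
— importantly — model misspecification. Because the generative mean model is
exactly the fitted model, classification at the ignition threshold is sharper
than with real observations (sensitivity near 1 rather than ≈ 0.91), and
truth-recovery tests are run with the zero-inflation switched off, since
recovery is only defined under the mean model. Passing tests therefore
demonstrate the correctness of the machinery, not the skill of the models on
real data.

## Problem sizes and determinism

Test and demo runs use desk-scale grids chosen for stable fits: the default
pipeline grid is 40 × 20 cells at 0.5° (800 cells; the fit requires at least
ten cells per parameter, i.e. 170), the shared test fixture 50 × 25, and
parameter-recovery replicates 100 × 50 (5000 cells, the size at which slope
standard errors are a few thousandths). Every stochastic stage is seeded;
identical configurations reproduce bit-identical datasets and identical
output-file hashes. The synthetic biome map is a rule-based stand-in
(latitude band × tree cover × GPP seasonality) that reproduces the structure
of a biome classification, not any real geography.

## Known limitations

Fire–vegetation feedbacks, lightning trends, interannual variability and
extreme events are out of scope by design; the models target long-term mean
regimes. The linear road-density model extrapolates poorly into regions with
no modern roads. All scenario machinery here runs on synthetic bundles;
applying it to real forcing archives requires only replacing the generator
outputs, as every stage consumes plain predictor matrices and monthly
climatology lists.
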