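---
title: "Models and methods behind birdhab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind birdhab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`birdhab` chains five statistical components: harmonic reflectance
regression with breakpoint detection, a presence-only maximum-entropy
species distribution model (SDM), annual habitat back-casting with
error-minimizing binarization, a hierarchical overdispersed-Poisson
abundance model, and territory-based impact accounting. This vignette
documents each model, its assumptions, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## The harmonic reflectance model

Surface reflectance for one pixel and spectral band is modelled as

$$R_t = A_0 + B_0 t + \sum_{k=1}^{3}\left[A_k\cos\!\left(\tfrac{2\pi k t}{T}\right) + B_k\sin\!\left(\tfrac{2\pi k t}{T}\right)\right], \qquad T = 365.25\ \text{d},$$

where $t$ is days since January 1 of the first analysis year. One clock
serves both the inter-annual trend ($B_0 t$) and the seasonal harmonics; the
phase origin is therefore fixed at the epoch start. Coefficients come from
ordinary least squares on the 8-column design $\{1, t, \cos, \sin, \ldots\}$
and require at least 8 observations at 8 distinct times (the design is
otherwise rank-deficient, which is raised as a typed error rather than
silently regularized). The RMSE uses $1/n$ normalization; $1/(n-p)$ is
available via `rmse_denom`.

**Break detection.** A segment's "running fit" is initialized on the first
12 observations, extended to cover at least two years (`min_span`,
730.5 d): with 16-day revisits a year of data leaves the three annual
harmonics nearly unconstrained, and residuals beyond the fit window are then
dominated by extrapolation error rather than real spectral change — two
years is the shortest window that made the false-alarm rate negligible at
the default 3×RMSE threshold. A break is declared at the first of 3
consecutive observations (`window`) whose absolute residuals exceed
`threshold_multiplier` (default 3) × RMSE in a majority (≥4 of 6) of bands.
These constants follow the continuous-change-detection convention and are
all configurable. Segments delimited by breaks are refit on their full
span; segments with fewer than 8 observations inherit the previous
segment's coefficients and carry an `inherited` flag.

**Features.** For each of six bands, the eight coefficients of the segment
covering a query year (evaluated at mid-year), followed by the six RMSEs:
54 variables. Features are piecewise constant between breaks; for
historical years the break-delimited segment covering that year supplies
the coefficients. That is an interpretation — a single-segment
model fit on a recent window and extrapolated backwards is the alternative —
and the break-delimited choice is the one that lets a clear-cut show up as
a feature change in the year it happens.

## The maximum-entropy SDM

Given presence feature vectors $x_1,\dots,x_m$ and background vectors, the
model is the Gibbs distribution $q_\lambda(x) \propto e^{\lambda\cdot f(x)}$
over background locations that minimizes

$$-\frac{1}{m}\sum_i \lambda\cdot f(x_i) + \log\!\!\sum_{\text{background}}\!\! e^{\lambda\cdot f(x)} + \sum_j \beta_j |\lambda_j|, \qquad \beta_j = \beta\, s_j/\sqrt{m},$$

with $s_j$ the presence-sample standard deviation of feature $j$ and
$\beta$ the regularization multiplier. Feature expansion is linear +
quadratic + all pairwise products of the min-max-scaled (to $[0,1]$, with
clamping outside the training range) raw features: $54 + 54 + 1431 = 1539$
derived features. Zero-variance features are kept as constant zero with
their weights locked.

Numerical choices:

- **Solver.** The objective is convex; it is minimized by monotone FISTA
  (proximal gradient with Nesterov momentum, backtracking line search and
  momentum restart on objective increase). Convergence is declared at a
  relative objective change below `tol` (default $10^{-8}$) and verified in
  tests against an independent bound-constrained L-BFGS solve of the same
  objective (KL divergence of the fitted Gibbs distributions $<10^{-6}$).
  Non-convergence raises an error carrying the final gradient norm.
- **Presences join the background** (`add_samples_to_background = TRUE`,
  the Maxent 3.4.x behaviour). Without this, a presence feature mean lying
  outside the background's range makes the penalized objective unbounded
  below; with it the objective is always coercive. The presence-sample sd
  in $\beta_j$ is floored at 5% of the pooled sd for the same reason.
- **Output.** Raw output is $e^{\lambda\cdot f(x)}/Z$; the default
  cloglog transform $1 - \exp(-e^{H} p(x))$ (with $H$ the entropy of the
  fitted background distribution) matches the convention of Maxent 3.4,
  maps the background-average score to $1-e^{-1}\approx 0.632$, and is
  invariant to background duplication.
- **Tuning.** $\beta$ is selected from a grid (convention: 0.1–2.0 in
  steps of 0.1) by training AUC, ties resolved toward the larger (more
  regularized) value. AUC is the exact Mann–Whitney rank statistic,
  counting ties as one half.
- **Validation.** Square spatial blocks partition the extent; whole blocks
  are assigned to the test set until its share is as close as possible to
  20%. The conventional "15 km² blocks" phrasing is ambiguous between a
  15 km edge and a 15 km² area (edge ≈ 3.87 km); the edge is a parameter
  and both readings are supported. Whether thresholds and beta selection
  should use the 80% training split or a 50% hold-out is likewise exposed
  as a parameter (`train_fraction`) rather than resolved.

## Habitat back-casting and accounting

The fitted SDM is applied to each year's 54-feature rasters (clamped with
the training scaling). Suitability is binarized at the cut point, over the
grid of observed validation scores, that minimizes $|FNR - FPR|$
(sensitivity = specificity), ties resolved toward higher sensitivity; the
Youden criterion $\max(Se + Sp)$ is available as an alternative since the
"minimize false positive and negative error" phrasing admits both. Areas
use 0.09 ha pixels; net change uses the first year as denominator. Route
buffers are rectangles 100 m each side of straight transects, rasterized by
pixel-centre-in-polygon with no partial-pixel weighting — deterministic and
exactly checkable against brute-force accumulation. Habitat-loss pixels
are attributed to clear-cutting or deforestation by overlap with the
disturbance schedule (deforestation takes precedence), remainder "other".

## The hierarchical abundance model

Route-level counts follow the overdispersed Poisson form

$$y_{r,t} \sim \text{Poisson}\!\left(\exp\left(\rho_r + \beta_1 (t - t_0) + \gamma_t + \omega_{o(r,t)} + \eta\, \text{first}_{r,t} + \alpha_H \tilde H_{r,t} + \alpha_\Delta \Delta\tilde H_{r,t} + \varepsilon_{r,t}\right)\right)$$

with hierarchical Normal route ($\rho$), observer ($\omega$), year
($\gamma$, sum-to-zero so the linear trend stays identified) and
observation-level overdispersion ($\varepsilon$) effects. Habitat
covariates are standardized internally (mean 0, sd 1 across route-years);
the fold-change summary $\exp(\alpha_H(\tilde H_{max} - \tilde H_{min}))$
uses the observed standardized range by default, with the range exposed as
a parameter because other scalings are defensible. The habitat-change
model can include or exclude the habitat-amount term; both variants are
supported.

Priors are weakly informative: effects Normal$(0,\sigma^2)$ with
half-Normal$(0,1)$ hyper-sds and $\beta_1 \sim$ Normal$(0, \sqrt{10})$ —
a deliberate departure from the inverse-gamma variance priors of the older
survey-trend literature, chosen for sampler stability. Sampling uses JAGS
(3 chains, default 2,000 draws after 1,000 warm-up, with the `glm` module's
block samplers). The fit fails loudly when the split-chain R-hat of any
reported effect parameter ($\beta_1$, $\alpha_H$, $\alpha_\Delta$, $\eta$)
exceeds 1.05. The gate deliberately excludes the variance hyperparameters:
the overdispersion sd in particular sits in a likelihood funnel and mixes
slowly under any Gibbs scheme at feasible chain lengths, while the effect
parameters it serves mix well; all R-hats are nevertheless computed and
reported, and `rhat_scope = "all"` restores the strict gate.

Trend conventions: annual percent change defaults to the "proportion"
reading ($100\beta_1$, so $-0.05$ is $-5\%$/yr), with the log-linear
$100(e^{\beta_1}-1)$ available. A population is "declining" when the 95%
credible interval for $\beta_1$ lies below zero. Ten-year trends refit the
model on the last ten years of data (rather than slicing the full-period
fit), and the cumulative change $100((1+\beta_1)^{10}-1)$ is flagged when
it falls below $-30\%$, the usual threatened-listing criterion.

## Impact accounting

Net habitat change per species (gains offsetting losses within species —
the net accounting the regional totals imply; a losses-only mode exists)
converts to breeding pairs via territory sizes: pairs lie between
loss/territory\_max and loss/territory\_min, individuals are exactly twice
pairs. The calculation assumes every habitat hectare is occupied by
territories; that assumption is strong and is stated wherever the numbers
are reported. The association regression (habitat change % on
mature-forest association score) is a Bayesian linear regression with flat
Normal priors and an optional per-successional-class (R/I/M) intercept —
the minimal model consistent with a hierarchical fit across species; its
residual sd is bounded below at $10^{-3}$ so that exactly collinear inputs
cannot drive the precision to overflow.

## The synthetic-data generator

The generator emulates the statistical structure each stage assumes:

- **Landscape.** 30 m pixels; per-year stand age and cover class
  (shade-tolerant old, naturally regenerating, plantation, non-forest).
  Each year forest pixels are clear-cut independently with probability
  `p_clearcut` (age resets; plantation with probability
  `plantation_fraction`, mirroring the planted/natural split of managed
  forests) or permanently deforested with probability `p_deforest` (kept
  small, consistent with deforestation contributing a few percent of
  change at most). Natural regeneration reaches the old class at `old_age`
  (default 60 yr). Defaults: 2%/yr clear-cut over 1985–2020, matching a
  roughly one-third cumulative harvest over 35 years.
- **Reflectance.** Each cover class has a harmonic coefficient library
  entry per band (bright aseasonal non-forest, dark moderately seasonal
  old forest, bright strongly seasonal regeneration, dark weakly seasonal
  evergreen plantations); series are the class curve at regular revisit
  dates (default 16 d) plus i.i.d. Gaussian noise (default sd 0.02
  reflectance units). Coefficients switch abruptly at disturbance.
- **Occurrences.** Points uniform over the grid; presence Bernoulli with
  occupancy logistic in stand age and cover class, so occupancy is strictly
  inside (0,1). Point density is a free parameter (`n_points`) since no
  density convention is assumed.
- **Counts.** Routes are straight 40 km transects (clipped to the grid)
  with 100 m buffers, placed uniformly; counts are drawn from exactly the
  hierarchical model the trends module fits, with the true habitat
  covariate taken as the occupancy-probability mass inside each buffer.
  Observers persist on a route and switch with probability 0.1/yr
  (about a ten-year tenure), with a first-year indicator.

One master seed spawns fixed per-component substreams, so landscape,
reflectance, occurrences and counts can be re-simulated independently and
identical seeds give bit-identical outputs.

What the generator does **not** emulate: radiative-transfer or sensor
physics, clouds and gaps in the revisit schedule, topography, road networks
(points are placed off-road uniformly; roadside placement bias is absent),
route sinuosity, and spatial autocorrelation of occupancy beyond what the
age/class mosaic induces. Passing tests therefore demonstrate that the
estimators recover the structures they model — not that those structures
exhaustively describe real Landsat or survey data.

## Problem sizes and test design

The test suite runs everything at desk scale, chosen so the full suite
completes in well under half an hour on one CPU: landscapes of 12×12 to
24×48 pixels, 6–35 simulated years, SDMs on a few hundred presences
against a few hundred background pixels, and hierarchical-model recovery
at 30 routes × 35 years over 20 replicates with a reduced sampler profile
(3 chains × 500 draws after 300 warm-up; the convergence gate is relaxed in
replicate loops and the recovery tolerances absorb the extra Monte Carlo
error). Deterministic operations are tested against independent oracles —
normal-equations solves, pair enumeration for AUC, exhaustive threshold
grids, brute-force buffer geometry, an independent convex solver for the
Maxent objective — and stochastic ones by parameter-recovery and
calibration simulations under fixed seeds.

## Known limitations

- Spatial inputs are in-memory tibbles/matrices on a planar 30 m grid;
  there is no projection handling or geospatial file I/O, and real raster
  stacks must be converted to the package's tabular form first.
- Break detection cannot flag disturbances within the first `min_span` of
  a segment, and inherits coefficients (flagged) for segments shorter than
  8 observations.
- The overdispersion-sd posterior should be read with its reported R-hat
  in mind (see above); the effect parameters are the reliable outputs.
- Maxent numerics follow the published objective, not any particular
  implementation's quirks; hinge/threshold/categorical features are
  deliberately absent.
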