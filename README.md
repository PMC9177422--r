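# birdhab

Forest degradation — the loss of old age classes and the simplification of
forest composition under intensive harvest, without any net loss of forest
cover — is hard to see in coarse land-cover maps, yet it can erase breeding
habitat for birds that depend on mature forest. `birdhab` implements a
species-centred analysis chain for quantifying that process and linking it
to population change, aimed at avian ecologists and conservation analysts
working with satellite reflectance time series, presence-only point counts
and roadside survey (BBS-style) route counts.

The chain has five stages, each usable on its own:

1. **Harmonic reflectance features.** Each pixel-band series is fit by
   ordinary least squares to

   `R_t = A0 + B0 t + Σ_{k=1..3} [ A_k cos(2πkt/T) + B_k sin(2πkt/T) ]`,
   `T = 365.25 d`,

   with breakpoint detection on the residuals (consecutive exceedances of a
   multiple of the segment RMSE in a majority of bands). The 8 coefficients
   per band for six bands, plus the six RMSEs, give the 54-variable feature
   vector used by the SDMs.
2. **Presence-only Maxent SDMs.** A from-scratch maximum-entropy model over
   background pixels with linear, quadratic and product features, per-feature
   L1 penalties `β_j = β s_j/√m`, a convex proximal-gradient solver,
   beta-multiplier tuning on a 0.1–2.0 grid, spatial-block 80/20 validation
   and rank-based AUC.
3. **Habitat back-casting.** The fitted model is applied to every year's
   feature rasters; suitability is binarized at the cut point that equalizes
   false-positive and false-negative rates, giving annual habitat areas,
   loss/gain maps, disturbance attribution and 200-m route-buffer series.
4. **Hierarchical abundance trends.** Route-level counts are modelled as an
   overdispersed Poisson regression (a route-level Sauer–Link variant) with
   year, observer, first-year, habitat-amount and habitat-change terms,
   sampled by MCMC (JAGS) with R-hat convergence gates.
5. **Impact accounting.** Net habitat losses divide by published territory
   sizes to bound breeding pairs lost (individuals are twice pairs), and a
   Bayesian regression relates habitat change to mature-forest association.

A synthetic-landscape simulator (`sim_config()`, `generate_landscape()`,
`simulate_reflectance()`, `simulate_occurrences()`, `simulate_bbs_counts()`)
generates all inputs with known ground truth, so every stage is verifiable
end to end without external data.

## Worked example

A complete synthetic run with an old-forest specialist and an early-seral
generalist on a heavily harvested landscape:

```r
library(birdhab)

cfg <- sim_config(seed = 11, rows = 24, cols = 48, years = 1991:2015,
                  p_clearcut = 0.05, plantation_fraction = 0.6,
                  revisit_days = 32,
                  bbs = list(n_routes = 12, alpha = 0.5, beta1 = -0.02))
run <- run_pipeline(cfg, n_points = 1200)
run
#> <pipeline_run> seed 11, 2 species, grid 24 x 48
#> # A tibble: 2 × 5
#>   species                beta threshold auc_test net_pct
#>   <chr>                 <dbl>     <dbl>    <dbl>   <dbl>
#> 1 oldforest_specialist    1       0.491    0.766   -42.6
#> 2 earlyseral_generalist   0.5     0.753    0.558    18.1
```

Reading the columns: `beta` is the selected Maxent regularization
multiplier, `threshold` the error-equalizing habitat cut point, `auc_test`
the spatially blocked hold-out AUC, and `net_pct` the net habitat change
between the first and last simulated year. Under heavy harvest the
old-forest specialist loses 42.6% of its habitat while the early-seral
species gains 18.1% — the signature of degradation rather than
deforestation. The fitted trend model ties abundance to habitat:

```r
old <- run$species$oldforest_specialist
old$trend$classification          #> "declining"
round(old$trend$fold_change$median, 2)   #> 3.42  (abundance ratio across the
                                         #>        observed habitat range)
run$impact$total                  # pairs/individuals lost across species
tidy(old$habitat_fit)             # posterior summary of all effects
autoplot(old$series)              # habitat-area trajectory
```

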