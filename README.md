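# phenomatch

Age-structured phenological-mismatch analysis for precocial chicks and
their invertebrate prey.

Climate change shifts the timing of seasonal resource pulses faster than
many consumers can track, decoupling the period of greatest consumer need
from the period of resource availability. Whether such mismatches matter
to *populations* depends on how the consumer–resource relationship is
modelled: conventional approaches reduce the consumer to a single
timepoint in development (the date of peak growth), while an
age-structured "whole demand" model follows every individual's rising
energetic need through development. phenomatch implements the full
analysis chain needed to compare these views for a precocial shorebird
system — Hudsonian-godwit-like chicks foraging on tundra invertebrates —
plus a synthetic-data generator with known ground truth so every stage is
testable without field data.

The pipeline:

1. **Resources** — invertebrate length records → inferred dry-mass series
   via taxon-specific allometry (`mass = a·length^b`), filtered to
   potential prey (adults, 1.5–9 mm, Collembola excluded); daily biomass
   (mg·transect⁻¹·day⁻¹) and median per-capita mass (mg); quadratic
   derivative-zero peak dates; interannual trends from linear mixed
   models with Gelman two-SD standardization.
2. **Growth** — fixed-asymptote logistic curves
   `m(t) = A₀ / (1 + e^{−K(t−Tᵢ)})` with `A₀ = 249` g, individual random
   intercepts on `K`, four candidate structures (constant/annual `K` and
   `Tᵢ`) ranked by conditional AIC; body condition index =
   observed / predicted mass gain; BCI modelled against resources with a
   penalized cubic age spline and conditional model averaging.
3. **Survival** — Bayesian hierarchical known-fate model of daily
   survival on the logit scale (JAGS): interval likelihood
   `∏ s_d` (survived) vs `1 − ∏ s_d` (died within), covariates at the
   3-day relocation cadence, age × prey-size interaction, random
   intercepts for brood/year/plot, WAIC comparison, Kuo–Mallick
   indicator-variable selection, and delta-method extrapolation
   `F = s²¹`, `SE(F) = 21·s²⁰·SE(s)` to annual fledging rates.
4. **Mismatch** — annual resource and consumer-demand curves
   (peak-demand and whole-demand with demand exponent θ, default 0.75),
   proportional-overlap index `Σ min(p_consumer, p_resource)`, peak-date
   difference, curve height, and four univariate models of annual
   fledging rates compared by AICc weights and adjusted R².

## Worked example

Simulate the default seven-season study and run the full analysis:

```r
library(phenomatch)

cfg    <- sim_config(seed = 1)                      # study conditions
inv    <- simulate_resources(cfg)                   # ~100k capture records
series <- aggregate_daily(filter_potential_prey(inv),
                          sampled_days = sim_sampled_days(cfg))
series
#> Daily resource series: 7 season(s), 462 sampled days
#>   biomass 0.0-372.6 mg/transect/day; median body mass 0.16-8.98 mg

ch <- simulate_chicks(cfg, series)                  # broods, masses, radios
h  <- build_encounter_histories(ch$chicks, ch$relocations, series)
h
#> Encounter histories: 114 chicks, 456 intervals; 86 deaths, 28 censored (fledged)

growth <- fit_growth_models(ch$masses)              # 4 structures, cAIC-ranked
fit <- fit_survival_mcmc(h, survival_model_spec(), mcmc_settings(seed = 1))
annual <- annual_fledging_rates(fit)
round(annual, 3)
#>   year   dsr dsr_se fledging fledging_se n_chicks
#> 1 2009 0.939  0.016    0.266       0.096       17
#> 2 2010 0.899  0.024    0.106       0.060       16
#> 3 2011 0.951  0.012    0.347       0.094       16
#> 4 2014 0.852  0.031    0.035       0.026       17
#> 5 2015 0.923  0.019    0.186       0.079       17
#> 6 2016 0.926  0.017    0.197       0.076       17
#> 7 2019 0.954  0.013    0.372       0.104       14

metrics <- mismatch_metrics(series, h, growth$top)  # the 4 annual metrics
fit_annual_models(metrics, annual)
#> Annual fledging-rate models (5 years):
#>          metric  slope    se adj_R2   AICc delta weight
#>   overlap_whole -0.955 0.352  0.614 14.734 0.000  0.571
#>    overlap_peak  1.728 0.773  0.500 16.033 1.299  0.298
#>    curve_height  0.000 0.000  0.156 18.651 3.916  0.081
#>  peak_diff_days -0.013 0.013 -0.027 19.629 4.895  0.049
```

Reading the output: annual daily survival rates (`dsr`) around 0.85–0.95
extrapolate to fledging rates of 3–37% across years; the whole-demand
overlap model carries the largest Akaike weight (0.57) and explains the
most variation in fledging (adjusted R² = 0.61), ahead of the
single-timepoint peak-demand overlap — the age-structured view of
consumer demand predicts reproductive output better than the
conventional one. Two seasons drop from the four-model comparison because
their narrow peak-demand histograms admit no concave quadratic for the
peak-date metric.

`run_pipeline(pipeline_config(fixture_dir = ...))` performs all of the
above from CSV inputs in one call and writes stage outputs plus a JSON
report; a thin command-line wrapper with the same stages lives in
`inst/scripts/phenomatch`. A small ready-made fixture ships under
`inst/extdata/fixture/`.

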