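---
title: "Models and methods behind phenomatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenomatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phenomatch implements an age-structured analysis of phenological mismatch
between precocial shorebird chicks and their invertebrate prey: from raw
invertebrate length records and chick radio-relocation histories to four
population-level mismatch metrics and their fit against annual fledging
rates. This vignette explains the models, the tunable parameters, the
synthetic-data generator, and the numerical and design choices made where
the methodology left room.

## 1. Resources: from length records to daily series

Invertebrate captures are identified to order and measured to the nearest
0.5 mm. Lengths become inferred dry mass through taxon-specific power laws
`mass = a * length^b` (mg, mm); the shipped `default_allometry()` table
contains generic literature-style coefficients with an `"all"` fallback row
and is meant to be replaced when calibrated coefficients are available.

Chicks are gape-limited surface foragers, so only adult invertebrates with
body lengths in the closed interval 1.5--9 mm count as potential prey, and
Collembola (primarily aquatic, rarely taken) are excluded. Both filter
bounds are arguments of `filter_potential_prey()`; the interval is treated
as closed at both ends because the protocol records lengths in 0.5-mm
steps, which makes the endpoints attainable observations.

`aggregate_daily()` treats the two transects as replicates: daily biomass
is the mean over transects of each transect's summed dry mass
(mg transect^-1 day^-1), and resource quality is the median per-capita dry
mass (mg) over the day's prey records. Days where only some transects
reported are averaged over the reporting transects rather than imputing a
zero, because a failed trap is indistinguishable from a lost sample in the
data schema; `n_transects` exposes the coverage. If the caller can supply
the set of days traps actually ran (`sampled_days`), days with no prey
catch enter the series as true zero-biomass days -- without that
information a zero catch and an unsampled day cannot be told apart.

Seasonal peaks come from the derivative-zero point of an ordinary
least-squares quadratic in day (`fit_quadratic_peak()`), the standard
estimator for unimodal seasonal abundance. Seasons sampled for fewer than
30 days are excluded from peak-timing analyses (`peak_eligible_years()`)
but retained for daily-level trends. Interannual trends use a linear mixed
model of the response on year (REML, lme4) with random intercepts for trap
type and for calendar day (the same day-of-year recurs across years);
responses are standardized internally by centring and dividing by two
standard deviations so that effect sizes are comparable across inputs, and
slopes are back-transformed to original units. Marginal and conditional
R-squared follow Nakagawa & Schielzeth. A singular mixed fit (all
random-effect variances at zero) falls back to ordinary least squares with
a warning rather than failing.

## 2. Growth: fixed-asymptote logistic curves and body condition

Chick mass at age `t` follows the logistic growth function

    m(t) = A0 / (1 + exp(-K (t - Ti)))

with the asymptote fixed at `A0 = 249` g, the mean adult mass with sexes
pooled. Fixing the asymptote is necessary because chicks are only observed
to 21 days, far below adult mass, and it makes `Ti` the age at which mass
crosses `A0/2 = 124.5` g at maximal growth rate. Four candidate structures
are fit by nonlinear mixed-effects estimation (nlme): `K` constant or
annual, `Ti` constant or annual, always with an individual random
intercept on `K` (the data lack sex information, and individual deviations
on `K` absorb much of the resulting heterogeneity). Each structure is
retried from jittered starting values (up to 100 restarts) because the
nonlinear optimizer is sensitive to initialization; a structure whose
mixed fit never converges is refit without the individual term via
Levenberg-Marquardt least squares and retained with zero random-effect
variance, which also handles noise-free data where a zero residual
variance breaks the usual convergence tests.

Candidates are ranked by conditional AIC. The effective degrees of freedom
are the trace of the hat matrix of the working linear model obtained by
linearizing the logistic curve at the estimates, with the random-effect
block ridge-penalized by `sigma^2 / sd_K^2`; the criterion is
`-2 * conditional logLik + 2 * (edf + 1)`. At zero random-effect variance
this reduces exactly to ordinary AIC, which the test suite asserts. When
the linearization is numerically unstable the structure's score downgrades
to a marginal small-sample AIC with a logged warning. Structures within 4
of the best form the candidate set.

The body condition index at a recapture is the observed mass gain since
the previous capture divided by the gain predicted over the same age
interval by the top model's population-level (year-specific) curve; the
population curve, not the chick's own deviation, is used so that a chick
persistently above or below the population curve shows up as condition
rather than being absorbed.

BCI is then modelled against resources in two stages. First the influence
timescale: additive fixed-effects models at the day of recapture and
trailing 1-, 3- and 7-day means pick the window with the lowest
small-sample AIC. Then every subset of {daily biomass, daily median prey
mass, hatch date} -- each with a penalized cubic regression spline of
chick age (mgcv, GCV-selected smoothness, basis dimension 8 by default,
reduced automatically when few distinct ages are observed) -- is ranked by
the same criterion, using the sum of effective degrees of freedom as the
parameter count so the spline penalty is respected. Covariate pairs with
|Pearson r| >= 0.7 are pruned (the later-listed covariate drops) before
fitting. If no model reaches weight 0.90, coefficients are conditionally
averaged across models within 4 of the best using Akaike weights. Years
without enough recaptures can be excluded via `exclude_years`.

## 3. Survival: Bayesian hierarchical known-fate model

Radio histories become interval-censored encounter histories: intervals
are cut at live relocations (hatch is a live contact at age 0); a carcass,
or three consecutive days without relocating the chick, ends the history
with a `died_within` interval; survival to 21 days (the radio lifespan) is
censoring as fledged. Chicks lost to human-caused mortality or day-0 radio
loss are excluded and counted.

Daily survival is logit-linear in standardized covariates: daily biomass
and daily median prey mass as trailing 3-day means (the relocation
cadence), hatch date, mid-interval age, and an age-by-prey-size
interaction (an age-by-biomass variant is available; an interaction may
only enter with both mains). The interval covariates are anchored on the
interval's last exposure day -- the days survived in interval
`(start, end]` are `start .. end-1` -- so a 3-day window aligns exactly
with a 3-day interval. The likelihood is the known-fate interval
likelihood: survived and censored intervals contribute `prod(s_d)`, death
intervals `1 - prod(s_d)` over their days, with no imputation of the death
day inside longer gaps. Because covariates are interval-constant, the JAGS
implementation evaluates `s^len` per interval, which is identical to the
per-day product and faster; the R-level `interval_log_likelihood()` keeps
the general per-day form and is tested against brute-force enumeration.

Priors are Normal(0, 10) on slope coefficients (diffuse on the
standardized logit scale, configurable), Uniform(0, 25) on random-effect
SDs, and Normal(0, sqrt(1000)) on the intercept. The model is
hierarchically centred: the year random intercepts carry the free mean
(the model intercept), while brood and plot intercepts are zero-centred.
A free hyper-mean on all three crossed factors alongside a fixed intercept
is unidentified and mixes catastrophically; centring on year preserves the
prior structure while keeping the intercept estimable. The plot intercepts
are additionally sum-to-zero constrained: with only two plots their free
mean is itself confounded with the intercept. Sampling uses
three chains of 5000 iterations after 600 adaptation and 1000 burn-in
iterations with every third sample kept; convergence requires every
Gelman-Rubin statistic below 1.1, and a non-converged fit is flagged but
returned. The per-parameter "Bayesian p" is `1 - 2 min(P(b>0), P(b<0))`,
the posterior evidence that a slope is non-zero.

Model comparison uses WAIC computed from the retained pointwise interval
log-likelihoods (`waic = -2 (lppd - p_waic)`, with the SE over pointwise
contributions), and variable selection uses Kuo-Mallick indicators:
each coefficient is multiplied by a Bernoulli(0.5) indicator and the
posterior mean of the indicator is the inclusion probability. The slab SD
for the selection run defaults to 0.75 rather than the diffuse estimation
prior: with a very diffuse slab the Lindley effect drives every inclusion
probability toward zero, while a slab comparable to plausible effect sizes
leaves a truly uninformative covariate near its 0.5 prior. Effects above
0.5 inclusion enter the selected model, with mains forced in under their
interactions.

Annual fledging rates extrapolate the year's exposure-weighted daily
survival rate to 21 days by the first-order delta method,
`F = s^21`, `SE(F) = 21 s^20 SE(s)`, validated against Monte-Carlo
propagation in the tests.

## 4. Mismatch: demand curves, overlap, and annual models

The annual resource curve is the daily proportion of the season's
biomass. Two consumer curves compete. The peak-demand curve is the
conventional single-timepoint model: each chick surviving to the growth
inflection contributes one unit on the calendar day `hatch + Ti`. The
whole-demand curve sums, over chicks alive each day, predicted mass raised
to a demand exponent `theta`; `theta = 0.75` by default (metabolic
allometry), with `theta = 1` (mass-proportional) and `theta = 0` (head
count) as named alternatives. The exact demand function is a modelling
choice; the default encodes that energetic demand rises with size but less
than proportionally, and the metric rankings can be recomputed under any
`theta`.

Overlap is the proportional-area index: the sum over days of the pointwise
minimum of the two daily-proportion curves (symmetric, in [0, 1], equal to
1 only for identical curves). Curve height is cumulative seasonal resource
availability: the area under the unnormalized biomass curve with each
sampled day a unit-width bar, i.e. the sum of daily biomass in mg.
Peak-date difference uses the same quadratic vertex estimator on both the
resource series and the peak-demand curve (resource minus demand, positive
when resources run late); because a spike histogram of a few dozen
inflection dates often admits no concave global quadratic, the pipeline
fits both vertices locally within 12 days of each curve's maximum.
Chicks with an interval-censored death contribute demand to the midpoint
of their death interval -- the least-informative point under the interval
likelihood.

Each of the four metrics enters a univariate ordinary least-squares model
of annual fledging rate, compared by small-sample AIC, Akaike weights and
adjusted R-squared over the common set of years with complete metrics
(at least four).

## 5. The synthetic-data generator

`sim_config()` defines a synthetic study whose defaults emulate the field
conditions: seven breeding seasons (2009--2011, 2014--2016, 2019) of
~66 days; a unimodal Gaussian-in-day biomass bump per year with
year-specific peak date and height (peaks near mid-June, heights
150--320 mg transect^-1 day^-1, width 12 days, optional per-year skew);
an order mix matching the observed assemblage composition (Araneae 20.5%,
Hymenoptera 18.4%, Coleoptera 17.5%, Diptera 16.2%, Acari 11.3%,
Hemiptera 7.7%, Collembola 8.3%) with order-specific lognormal lengths; a
12% larval fraction; pitfall traps through 2012 and malaise traps from
2014. Prey size can drift with the season (`length_season_trend`) or peak
with the biomass bump (`length_peak_boost`); in either case the Poisson
count intensity is compensated analytically (truncated-lognormal moments
of the filtered assemblage) so the expected filtered biomass keeps the
stated Gaussian shape -- resource quantity and quality can be varied
independently.

Chicks hatch around a per-year mean date (default day 161, SD 4 days, one
or two radio chicks per brood), grow along the logistic curve with
`K = 0.18`, `Ti = 12`, individual SD 0.015 on `K`, and 3-g measurement
noise at irregular recaptures. Survival is drawn day by day (Bernoulli per
day, so the interval likelihood is exercised honestly) from the
logit-linear model applied to that day's 3-day-averaged covariates,
standardized with constants stored in the ground truth so estimates are
directly comparable to the generating coefficients. The default
coefficients are arbitrary round values chosen so that roughly a fifth of
chicks fledge, matching the magnitude of observed shorebird fledging
rates; they are not estimates from any data set. Relocations are emitted
every 3 days, deaths are observed at the next scheduled relocation, and
survivors are censored at 21 days.

What the generator does not emulate: spatial structure and movement,
predator dynamics, sex-specific growth, brood-level survival
heterogeneity, renesting cohorts, radio failure, and resource-dependent
growth (masses follow the logistic curve regardless of the resource
series; only survival responds to resources). Passing tests therefore
demonstrate that the estimators recover the generating processes they
model, not that real data meet those assumptions.

## 6. Study conditions used by the test suite

Test problem sizes are the package's own choices, balancing statistical
resolution against a single-core run: survival credible-interval coverage
uses 200 chicks per seed over 20 seeds with a correctly specified
fixed-effects model (the generator draws no group effects; the
random-intercept machinery is exercised by the pipeline and selection
tests) and shortened chains (2 x 1800 after burn-in); growth-structure
ranking uses 100 chicks over 100 seeds; trend coverage uses 100
replicates of 9 seasons of daily data.

The whole-demand ranking scenario deserves its own note. When simulated
years differ only in resource timing, the whole-demand and peak-demand
overlaps are almost perfectly collinear (both are smooth monotone
functions of the timing offset) and which one best predicts fledging is a
coin flip at field-realistic cohort sizes. The regime in which the
age-structured curve genuinely outranks the single-timepoint curve -- and
the regime the whole-demand model exists for -- is one where consumer
demand structure varies too: the test scenario crosses one-sided resource
timing variation with independently varying brood synchrony (per-year
hatch SD 2--9 days) and lets prey size co-move with the resource bump, so
that fledging is driven by prey size late in development through the
age-by-size interaction. Brood synchrony corrupts the single-date
peak-demand reading while leaving the whole-demand curve informative,
reproducing the qualitative separation between the two models.

## 7. Numerical choices and degenerate inputs

* `standardize_gelman()` requires two distinct values; encounter-history
  construction centres (scale 1) any degenerate covariate instead, so a
  single-chick history is still usable.
* `rolling_mean()` skips missing days rather than interpolating;
  interpolation would manufacture resource information on unsampled days.
  The prey-size covariate falls back from a 3- to a 7-day window and then
  the year median, because the size signal moves slowly; biomass does not
  fall back, and a chick occupying truly unsampled days is an error.
* Quadratic peak fits require three distinct days and a negative
  curvature; monotone series raise an error rather than extrapolating a
  vertex outside the season.
* Zero-variance random effects: the trend model falls back to OLS; the
  growth fit falls back to fixed-effects least squares; conditional AIC
  collapses to AIC.
* All generator stages draw from their own RNG stream derived from the
  master seed by fixed offsets, so partial reruns are stable, and the
  caller's RNG state is saved and restored.
* MCMC chains are seeded per chain from the settings seed, making every
  fit byte-reproducible under fixed settings.

## 8. Known limitations

* The conditional AIC uses a first-order linearization of the logistic
  curve; for strongly nonlinear fits with large individual variation the
  effective degrees of freedom are approximate.
* The intercept of the survival model is only estimable relative to the
  mean of the year intercepts (hierarchical centring); per-year survival
  summaries marginalize correctly, but the reported `mu` should be read
  as the year-level mean.
* The peak-demand curve is a histogram of discrete inflection dates; at
  small cohort sizes its overlap and vertex estimates are noisy, which is
  intrinsic to the single-timepoint model rather than to this
  implementation.
* With only two study plots, the plot random-intercept SD is weakly
  identified and mixes slowly; inferences about it should not be taken
  seriously (the paper's design shares this limit).
* Model weights across the four annual models are computed on the common
  years with all metrics defined; a year whose peak-date difference is
  undefined drops from all four models to keep the comparison valid.
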