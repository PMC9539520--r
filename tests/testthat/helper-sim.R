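# Shared simulation helpers for the test suite. Problem sizes are kept
# modest so the whole suite runs on one core; the configurations below
# are the study conditions the tests probe, built once per call from a
# seed so every test is reproducible.

# Small four-season configuration used for survival-model tests: moderate
# resource variation among years, a declining seasonal prey-size trend,
# and ~200 radio-tagged chicks.
survival_test_config <- function(seed, beta, n_broods = 34, trend = -0.02) {
  sim_config(
    years = 2009:2012,
    resource_peak_day = c(162, 170, 158, 166),
    resource_peak_height = c(250, 180, 220, 280),
    length_season_trend = trend,
    n_broods = n_broods, prob_two_chicks = 0.5,
    hatch_mean = 161, hatch_sd = 4,
    beta = beta, seed = seed)
}

# Simulate encounter histories with the generator's own standardization
# constants, so estimated coefficients are directly comparable to the
# generating betas.
sim_histories <- function(seed, beta, n_broods = 34, trend = -0.02) {
  cfg <- survival_test_config(seed, beta, n_broods, trend)
  inv <- simulate_resources(cfg)
  series <- aggregate_daily(filter_potential_prey(inv),
                            sampled_days = sim_sampled_days(cfg))
  ch <- simulate_chicks(cfg, series)
  h <- build_encounter_histories(ch$chicks, ch$relocations, series,
                                 scaling = ch$truth$scaling)
  attr(h, "truth") <- ch$truth
  h
}

# Short MCMC settings for tests that only need a rough posterior.
quick_mcmc <- function(seed, chains = 2, iterations = 1200, adapt = 300,
                       burn_in = 400, thin = 3) {
  mcmc_settings(chains = chains, iterations = iterations, adapt = adapt,
                burn_in = burn_in, thin = thin, seed = seed)
}

# Mass-capture data from the logistic growth curve with optional annual
# inflection offsets, for growth-model structure tests.
sim_mass_captures <- function(seed, n = 100, Ti_offsets = c(0, 0, 0),
                              K = 0.18, Ti = 12, K_sd = 0.015, noise = 3) {
  set.seed(seed)
  yrs <- 2009 + seq_along(Ti_offsets) - 1
  out <- lapply(seq_len(n), function(i) {
    y <- sample(seq_along(yrs), 1)
    Ki <- K + rnorm(1, 0, K_sd)
    ages <- sort(sample(0:21, 4))
    data.frame(chick_id = sprintf("c%03d", i), year = yrs[y], age = ages,
               mass_g = logistic_mass(ages, Ki, Ti + Ti_offsets[y]) +
                 rnorm(length(ages), 0, noise))
  })
  do.call(rbind, out)
}

# Tiny daily resource series built by hand for curve/metric tests.
toy_series <- function(years, days, biomass, bodymass = 1) {
  s <- data.frame(year = years, day = days, biomass_mg = biomass,
                  median_bodymass_mg = bodymass,
                  n_records = 1L, n_transects = 1L)
  class(s) <- c("daily_resource_series", "data.frame")
  s
}
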