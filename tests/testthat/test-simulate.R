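small_cfg <- function(...) {
  args <- list(years = 2009:2010, resource_peak_day = c(160, 168),
               resource_peak_height = 120, n_broods = 6, hatch_mean = 158,
               season_start = 140, season_end = 190)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("the generator is reproducible and respects degenerate settings", {
  a <- simulate_resources(small_cfg(seed = 4))
  b <- simulate_resources(small_cfg(seed = 4))
  expect_identical(a, b)
  d <- simulate_resources(small_cfg(seed = 5))
  expect_false(identical(a, d))
  # zero peak height -> zero records
  z <- simulate_resources(small_cfg(resource_peak_height = 0, seed = 4))
  expect_equal(nrow(z), 0)
  # trap type follows the year rule
  expect_true(all(a$trap_type[a$year <= 2012] == "pitfall"))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(order_mix = c(Araneae = 0.6, Diptera = 0.6)), "sum to 1")
  expect_error(sim_config(season_start = 200, season_end = 150), "precede")
  expect_error(sim_config(fledge_age = 0), "positive")
  expect_error(sim_config(hatch_sd = -1), "non-negative")
})

test_that("latent growth hits the inflection identity and mass noise is applied", {
  cfg <- small_cfg(K_indiv_sd = 0, mass_obs_sd = 0, seed = 6)
  expect_equal(logistic_mass(cfg$growth_Ti, cfg$growth_K, cfg$growth_Ti, cfg$A0),
               cfg$A0 / 2)
  inv <- simulate_resources(cfg)
  series <- aggregate_daily(filter_potential_prey(inv),
                            sampled_days = sim_sampled_days(cfg))
  ch <- simulate_chicks(cfg, series)
  at_ti <- ch$masses[ch$masses$age == cfg$growth_Ti, ]
  if (nrow(at_ti) > 0) expect_equal(at_ti$mass_g, rep(cfg$A0 / 2, nrow(at_ti)))
})

test_that("constant daily survival yields the closed-form fledging fraction", {
  cfg <- sim_config(n_broods = 50, prob_two_chicks = 0.5,
                    beta = c(intercept = qlogis(0.9), biomass = 0, bodymass = 0,
                             hatch = 0, age = 0, age_bodymass = 0),
                    seed = 12)
  inv <- simulate_resources(cfg)
  series <- aggregate_daily(filter_potential_prey(inv),
                            sampled_days = sim_sampled_days(cfg))
  ch <- simulate_chicks(cfg, series)
  n <- nrow(ch$truth$chicks)
  expect_gte(n, 500)
  p <- 0.9^21
  phat <- mean(ch$truth$chicks$fledged)
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
  # survival identically 1 -> every chick fledges
  cfg1 <- small_cfg(beta = c(intercept = 50, biomass = 0, bodymass = 0,
                             hatch = 0, age = 0, age_bodymass = 0), seed = 3)
  inv1 <- simulate_resources(cfg1)
  s1 <- aggregate_daily(filter_potential_prey(inv1),
                        sampled_days = sim_sampled_days(cfg1))
  ch1 <- simulate_chicks(cfg1, s1)
  expect_true(all(ch1$truth$chicks$fledged))
})

test_that("fixture sets round-trip losslessly and rerun identically", {
  cfg <- small_cfg(seed = 8)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  p1 <- write_fixture_set(cfg, d1)
  p2 <- write_fixture_set(cfg, d2)
  expect_true(all(file.exists(p1)))
  # identical content for identical (config, seed)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]), label = nm)
  }
  # re-read tables match the in-memory originals
  inv <- read_invertebrates(p1["invertebrates"])
  chk <- read_chicks(p1["chicks"])
  rel <- read_relocations(p1["relocations"])
  mas <- read_masses(p1["masses"], chk)
  raw <- simulate_resources(cfg)
  expect_equal(nrow(inv), nrow(raw))
  expect_equal(inv$length_mm, raw$length_mm)
  expect_equal(inv$day, raw$day)
  series <- aggregate_daily(filter_potential_prey(raw),
                            sampled_days = sim_sampled_days(cfg))
  ch <- simulate_chicks(cfg, series)
  expect_equal(chk$hatch_day, ch$chicks$hatch_day)
  expect_equal(nrow(rel), nrow(ch$relocations))
  expect_equal(nrow(mas), nrow(ch$masses))
  # empty brood setting still writes valid, empty chick-side files
  p0 <- write_fixture_set(small_cfg(n_broods = 0, seed = 8),
                          file.path(tempdir(), "fx0"))
  expect_equal(nrow(read_chicks(p0["chicks"])), 0)
  expect_gt(nrow(read_invertebrates(p0["invertebrates"])), 0)
})

test_that("quadratic peak estimation recovers the generating peak dates", {
  # generator-vs-estimator round trip across seeds and years
  errs <- c()
  for (seed in 1:20) {
    cfg <- small_cfg(seed = seed)
    inv <- simulate_resources(cfg)
    series <- aggregate_daily(filter_potential_prey(inv),
                              sampled_days = sim_sampled_days(cfg))
    for (y in cfg$years) {
      p <- tryCatch(fit_quadratic_peak(series, y), error = function(e) NULL)
      if (!is.null(p)) {
        errs <- c(errs, abs(p$peak_day - cfg$resource_peak_day[as.character(y)]))
      }
    }
  }
  expect_gte(length(errs), 36)
  expect_lt(mean(errs), 2)
})
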