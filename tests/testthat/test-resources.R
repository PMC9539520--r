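make_records <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

test_that("prey filter keeps adults in the closed 1.5-9 mm band and drops Collembola", {
  r <- make_records(
    year = 2009, day = 150, transect = "T1", trap_type = "pitfall",
    order = c("Diptera", "Diptera", "Collembola", "Diptera", "Diptera",
              "Araneae", "Acari"),
    life_stage = c("adult", "larva", "adult", "adult", "adult", "adult", "adult"),
    length_mm = c(5, 5, 5, 1.5, 9, 1.0, 9.5))
  out <- filter_potential_prey(r)
  # adult Diptera 5 mm kept; larva dropped; Collembola dropped;
  # both interval endpoints kept; out-of-band lengths dropped
  expect_equal(nrow(out), 3)
  expect_true(all(out$order != "Collembola"))
  expect_true(all(out$life_stage == "adult"))
  expect_setequal(out$length_mm, c(5, 1.5, 9))
  # empty in, empty out; order of survivors preserved
  expect_equal(nrow(filter_potential_prey(r[0, ])), 0)
  expect_equal(out$length_mm, c(5, 1.5, 9))
})

test_that("daily aggregation averages transects and takes per-capita medians", {
  tab <- data.frame(order = "all", a = 1, b = 1)  # mass = length
  r <- make_records(
    year = 2009, day = c(150, 150, 150, 151),
    transect = c("T1", "T1", "T2", "T1"),
    order = "Diptera", life_stage = "adult",
    length_mm = c(4, 6, 20, 7))
  s <- aggregate_daily(r, tab)
  # day 150: transect sums {10, 20} -> mean 15; medians over {4, 6, 20} -> 6
  expect_equal(s$biomass_mg[s$day == 150], 15)
  expect_equal(s$median_bodymass_mg[s$day == 150], 6)
  expect_equal(s$n_transects[s$day == 150], 2)
  # day 151 has records on 1 of 2 transects: mean over reporting transects
  expect_equal(s$biomass_mg[s$day == 151], 7)
  expect_equal(s$n_transects[s$day == 151], 1)
})

test_that("aggregation conserves mass and is permutation invariant", {
  set.seed(42)
  n <- 200
  r <- make_records(
    year = sample(2009:2010, n, TRUE), day = sample(150:160, n, TRUE),
    transect = sample(c("T1", "T2"), n, TRUE),
    order = "Diptera", life_stage = "adult",
    length_mm = runif(n, 2, 8))
  s <- aggregate_daily(r)
  total_from_series <- sum(s$biomass_mg * s$n_transects)
  total_direct <- sum(length_to_dry_mass(r$length_mm, r$order))
  expect_equal(total_from_series, total_direct, tolerance = 1e-9)
  perm <- r[sample(n), ]
  expect_equal(as.data.frame(aggregate_daily(perm)), as.data.frame(s))
})

test_that("sampled days without prey enter the series as zero catches", {
  r <- make_records(year = 2009, day = 150, transect = "T1",
                    order = "Diptera", life_stage = "adult", length_mm = 5)
  s <- aggregate_daily(r, sampled_days = data.frame(year = 2009, day = 150:152))
  expect_equal(nrow(s), 3)
  expect_equal(s$biomass_mg[s$day == 151], 0)
  expect_true(is.na(s$median_bodymass_mg[s$day == 152]))
  expect_equal(s$n_records[s$day == 151], 0L)
})

test_that("trailing rolling mean handles windows, identity, and gaps", {
  s <- toy_series(2009, c(150, 151, 152, 155), c(1, 2, 3, 10))
  expect_equal(rolling_mean(s, 2009, 152, 3), 2)        # {1,2,3}
  expect_equal(rolling_mean(s, 2009, 152, 1), 3)        # day's own value
  expect_equal(rolling_mean(s, 2009, 155, 3), 10)       # gap days skipped
  expect_true(is.na(rolling_mean(s, 2009, 149, 1)))     # nothing in window
  const <- toy_series(2009, 150:160, 7)
  for (w in c(1, 3, 7)) expect_equal(rolling_mean(const, 2009, 158, w), 7)
})

test_that("quadratic peak estimator matches the analytic vertex", {
  d <- 80:120
  s <- toy_series(2009, d, 10 + 4 * d - 0.02 * d^2)
  p <- fit_quadratic_peak(s, 2009)
  expect_equal(p$peak_day, 100, tolerance = 1e-9)
  # symmetric data about day 50
  d2 <- 30:70
  s2 <- toy_series(2010, d2, exp(-(d2 - 50)^2 / 100))
  expect_equal(fit_quadratic_peak(s2, 2010)$peak_day, 50, tolerance = 1e-6)
  # monotone data has no interior maximum
  s3 <- toy_series(2011, 1:30, 1:30)
  expect_error(fit_quadratic_peak(s3, 2011), "no interior maximum")
  expect_error(fit_quadratic_peak(toy_series(2012, c(1, 2), 1:2), 2012),
               "3 distinct days")
})

test_that("Gelman standardization centres and halves the scale", {
  # sd(1:3) = 1, so (x - 2) / (2 * 1) = (-0.5, 0, 0.5)
  z <- standardize_gelman(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-0.5, 0, 0.5))
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(50, runif(1, -10, 10), runif(1, 0.5, 5))
    z <- standardize_gelman(x)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 0.5, tolerance = 1e-12)
    # affine invariance up to sign
    a <- runif(1, -3, 3); b <- runif(1, 0.1, 4)
    expect_equal(as.numeric(standardize_gelman(a + b * x)), as.numeric(z),
                 tolerance = 1e-9)
    expect_equal(as.numeric(standardize_gelman(a - b * x)), -as.numeric(z),
                 tolerance = 1e-9)
  }
  expect_error(standardize_gelman(rep(2, 5)), "distinct")
})

test_that("trend model recovers a noise-free slope exactly and falls back cleanly", {
  d <- data.frame(year = rep(2009:2015, each = 4))
  d$resp <- 100 - 2 * (d$year - 2009)
  tr <- suppressWarnings(fit_trend(d, "resp", random = character(0)))
  expect_equal(tr$slope, -2, tolerance = 1e-9)
  expect_true(tr$relevant)
  # grouping columns absent from the data are dropped, not an error
  tr2 <- suppressWarnings(fit_trend(d, "resp"))
  expect_equal(tr2$slope, -2, tolerance = 1e-8)
  expect_error(fit_trend(d[d$year == 2009, ], "resp"), "2 years")
})

test_that("shortened seasons are excluded from peak-timing eligibility", {
  s <- rbind(toy_series(2009, 140:200, 5), toy_series(2012, 150:155, 5))
  expect_equal(peak_eligible_years(s), 2009)
})
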