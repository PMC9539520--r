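const_fit <- structure(list(K_structure = "constant", Ti_structure = "constant",
                            A0 = 249, K_fixed = c(`2009` = 0.18),
                            Ti_fixed = c(`2009` = 10), K_indiv = numeric(0),
                            sd_K = 0, sigma = 1, logLik = NA, cAIC = NA,
                            edf = NA, caic_type = "conditional", engine = "nls",
                            n = 0), class = "growth_fit")
sched <- function(hatch, end, year = 2009) {
  data.frame(chick_id = sprintf("s%02d", seq_along(hatch)), year = year,
             hatch_day = hatch, end_age = end)
}

test_that("resource curve normalizes, is scale invariant, and rejects zero seasons", {
  s <- toy_series(2009, 150:159, 5)
  rc <- resource_curve(s, 2009)
  expect_equal(rc$proportion, rep(0.1, 10))
  s2 <- s; s2$biomass_mg <- s2$biomass_mg * 7
  expect_equal(resource_curve(s2, 2009)$proportion, rc$proportion)
  expect_equal(sum(resource_curve(toy_series(2009, 150:170,
    runif(21, 0, 5)), 2009)$proportion), 1, tolerance = 1e-12)
  expect_error(resource_curve(toy_series(2009, 150:155, 0), 2009), "all-zero")
})

test_that("peak-demand curve is the frequency of inflection dates of survivors", {
  # five chicks hatched the same day -> a single spike at hatch + Ti
  pc <- peak_demand_curve(sched(rep(155, 5), rep(21, 5)), const_fit, 2009)
  expect_equal(pc$day, 165)
  expect_equal(pc$proportion, 1)
  # a chick dying before the inflection age contributes nothing
  pc2 <- peak_demand_curve(sched(c(155, 155), c(21, 4)), const_fit, 2009)
  expect_equal(pc2$proportion, 1)
  # two equal cohorts four days apart -> bimodal 0.5/0.5
  pc3 <- peak_demand_curve(sched(c(155, 155, 159, 159), rep(21, 4)),
                           const_fit, 2009)
  expect_equal(pc3$day, c(165, 169))
  expect_equal(pc3$proportion, c(0.5, 0.5))
  expect_error(peak_demand_curve(sched(155, 21, year = 2009), const_fit, 2011),
               "no chicks")
})

test_that("whole-demand curve weights alive chicks by mass^theta", {
  # one chick alive two days with masses m0, m1 and theta = 1
  one <- sched(155, 1)
  wc <- whole_demand_curve(one, const_fit, 2009, theta = 1)
  m <- predict_mass(const_fit, 0:1, 2009)
  expect_equal(wc$day, c(155, 156))
  expect_equal(wc$proportion, m / sum(m))
  # theta = 0 reduces to the daily count of alive chicks
  two <- sched(c(155, 156), c(1, 1))
  wc0 <- whole_demand_curve(two, const_fit, 2009, theta = 0)
  expect_equal(wc0$day, 155:157)
  expect_equal(wc0$proportion, c(1, 2, 1) / 4)
  # whole-demand peaks later than peak-demand when the cohort outlives Ti
  coh <- sched(rep(155, 30), rep(21, 30))
  wd <- whole_demand_curve(coh, const_fit, 2009, theta = 0.75)
  pd <- peak_demand_curve(coh, const_fit, 2009)
  expect_gt(wd$day[which.max(wd$proportion)], pd$day[which.max(pd$proportion)])
})

test_that("overlap index has its analytic values and symmetry", {
  u1 <- structure(data.frame(year = 2009, day = 150:159, proportion = 0.1),
                  class = c("phenology_curve", "data.frame"))
  u2 <- structure(data.frame(year = 2009, day = 155:164, proportion = 0.1),
                  class = c("phenology_curve", "data.frame"))
  u3 <- structure(data.frame(year = 2009, day = 170:179, proportion = 0.1),
                  class = c("phenology_curve", "data.frame"))
  expect_equal(overlap_index(u1, u1), 1)
  expect_equal(overlap_index(u1, u3), 0)
  expect_equal(overlap_index(u1, u2), 0.5)
  expect_equal(overlap_index(u2, u1), overlap_index(u1, u2))
  bad <- u2; bad$year <- 2010
  expect_error(overlap_index(u1, bad), "different years")
})

test_that("curve height is the unit-day area and is additive", {
  expect_equal(curve_height(toy_series(2009, 150:159, 100), 2009), 1000)
  s <- toy_series(2009, c(150:154, 170:174), c(rep(10, 5), rep(20, 5)))
  expect_equal(curve_height(s, 2009), 50 + 100)
  expect_equal(curve_height(toy_series(2009, 150:159, 0), 2009), 0)
})

test_that("peak-date difference is zero at identity, shifts with translation, antisymmetric", {
  d <- 150:190
  bump <- exp(-(d - 170)^2 / 50)
  s <- toy_series(2009, d, bump)
  self_curve <- resource_curve(s, 2009)
  expect_equal(peak_date_difference(s, self_curve, 2009), 0, tolerance = 1e-6)
  shifted <- structure(data.frame(year = 2009, day = d - 7,
                                  proportion = bump / sum(bump)),
                       class = c("phenology_curve", "data.frame"))
  expect_equal(peak_date_difference(s, shifted, 2009), 7, tolerance = 1e-6)
  # swapping the roles negates the difference (two series, same estimator)
  s2 <- toy_series(2009, d, exp(-(d - 163)^2 / 50))
  c1 <- resource_curve(s, 2009); c2 <- resource_curve(s2, 2009)
  d12 <- peak_date_difference(s, c2, 2009)
  d21 <- peak_date_difference(s2, c1, 2009)
  expect_equal(d12, -d21, tolerance = 1e-6)
  expect_equal(d12, 7, tolerance = 0.5)
})

test_that("annual model table ranks a perfectly linear metric first", {
  set.seed(8)
  m <- data.frame(year = 2009:2016,
                  overlap_whole = runif(8, 0.3, 0.8),
                  overlap_peak = runif(8),
                  peak_diff_days = rnorm(8, 0, 8),
                  curve_height = runif(8, 4000, 9000))
  fl <- data.frame(year = 2009:2016,
                   fledging = 0.05 + 0.5 * m$overlap_whole)
  tab <- fit_annual_models(m, fl)
  expect_equal(tab$metric[1], "overlap_whole")
  expect_gt(tab$weight[1], 0.9)
  expect_equal(tab$adj_R2[1], 1, tolerance = 1e-9)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_error(fit_annual_models(m[1:3, ], fl[1:3, ]), "4 years")
  # metrics are invariant to chick order in the schedule
  coh <- sched(155 + (0:9), rep(21, 10))
  s <- toy_series(2009, 150:200, exp(-(150:200 - 170)^2 / 60))
  m1 <- suppressWarnings(mismatch_metrics(s, coh, const_fit))
  m2 <- suppressWarnings(mismatch_metrics(s, coh[sample(10), ], const_fit))
  expect_equal(as.data.frame(m1), as.data.frame(m2))
})
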