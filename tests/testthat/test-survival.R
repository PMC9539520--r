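toy_chicks <- function(...) {
  data.frame(chick_id = "a", brood_id = "b1", plot = "North", year = 2009,
             hatch_day = 150, ...)
}
full_series <- toy_series(2009, 140:200, 100, bodymass = 1.5)

test_that("encounter histories follow the relocation fate rules", {
  rel <- data.frame(chick_id = "a", day = 150 + c(3, 6, 8),
                    status = c("alive", "alive", "dead"))
  h <- build_encounter_histories(toy_chicks(), rel, full_series)
  expect_equal(h$start_age, c(0, 3, 6))
  expect_equal(h$end_age, c(3, 6, 8))
  expect_equal(h$fate, c("survived", "survived", "died_within"))
  # alive through day 21 -> final interval censored (fledged)
  rel2 <- data.frame(chick_id = "a", day = 150 + seq(3, 21, 3), status = "alive")
  h2 <- build_encounter_histories(toy_chicks(), rel2, full_series)
  expect_equal(tail(h2$fate, 1), "censored")
  expect_equal(max(h2$end_age), 21)
  # three consecutive missing days -> death interval ending on the third
  rel3 <- data.frame(chick_id = "a", day = 150 + c(3, 6, 9, 10, 11, 12),
                     status = c("alive", "alive", rep("missing", 4)))
  h3 <- build_encounter_histories(toy_chicks(), rel3, full_series)
  expect_equal(tail(h3$fate, 1), "died_within")
  expect_equal(max(h3$end_age), 11)  # run 9,10,11 completes the 3-day rule
  # non-consecutive missing days do not trigger the rule
  rel4 <- data.frame(chick_id = "a", day = 150 + c(3, 6, 9, 11, 13),
                     status = c("alive", "alive", "missing", "missing", "missing"))
  h4 <- build_encounter_histories(toy_chicks(), rel4, full_series)
  expect_false(any(h4$fate == "died_within"))
})

test_that("exclusions and malformed relocations are handled", {
  chicks <- rbind(toy_chicks(), toy_chicks())
  chicks$chick_id <- c("a", "b")
  chicks$exclude <- c(FALSE, TRUE)
  rel <- data.frame(chick_id = c("a", "b"), day = 153, status = "alive")
  h <- build_encounter_histories(chicks, rel, full_series)
  expect_equal(unique(h$chick_id), "a")
  expect_equal(attr(h, "excluded"), "b")
  expect_error(build_encounter_histories(
    toy_chicks(), data.frame(chick_id = "a", day = 149, status = "alive"),
    full_series), "before hatch")
  expect_error(build_encounter_histories(
    toy_chicks(), data.frame(chick_id = "zz", day = 153, status = "alive"),
    full_series), "unknown chick")
})

test_that("interval likelihood matches closed forms and brute-force enumeration", {
  h <- data.frame(len = 3, fate = "survived")
  expect_equal(interval_log_likelihood(h, rep(0.9, 3)), log(0.9^3))
  hd <- data.frame(len = 3, fate = "died_within")
  expect_equal(interval_log_likelihood(hd, rep(0.9, 3)), log(1 - 0.9^3))
  expect_error(interval_log_likelihood(h, c(0.9, 1, 0.9)), "strictly")
  expect_error(interval_log_likelihood(h, rep(0.9, 2)), "per occupied day")

  # likelihood dichotomy: exp(survived) + exp(died) = 1 on any interval
  set.seed(5)
  for (i in 1:10) {
    s <- runif(4, 0.5, 0.99)
    ls <- interval_log_likelihood(data.frame(len = 4, fate = "survived"), s)
    ld <- interval_log_likelihood(data.frame(len = 4, fate = "died_within"), s)
    expect_equal(exp(ls) + exp(ld), 1, tolerance = 1e-12)
  }

  # enumeration oracle on a two-interval history: sum over every possible
  # death day of the product of daily Bernoulli outcomes
  hist2 <- data.frame(len = c(2, 2), fate = c("survived", "died_within"))
  s <- c(0.9, 0.8, 0.7, 0.6)
  p_enum <- 0
  for (death_day in 3:4) {  # death occurs within the second interval
    p <- prod(s[seq_len(death_day - 1)]) * (1 - s[death_day])
    p_enum <- p_enum + p
  }
  expect_equal(interval_log_likelihood(hist2, s), log(p_enum), tolerance = 1e-12)
})

test_that("delta-method fledging extrapolation matches Monte Carlo", {
  f <- dsr_to_fledging(1, 0)
  expect_equal(f$fledging, 1)
  expect_equal(f$se, 0)
  f2 <- dsr_to_fledging(0.9, 0.01)
  expect_equal(f2$fledging, 0.9^21, tolerance = 1e-12)
  expect_equal(f2$se, 21 * 0.9^20 * 0.01, tolerance = 1e-12)
  expect_error(dsr_to_fledging(1.2, 0.01), "0, 1")
  set.seed(9)
  for (s in c(0.85, 0.9, 0.95, 0.99)) {
    draws <- rnorm(1e5, s, 0.01)^21
    expect_lt(abs(dsr_to_fledging(s, 0.01)$se - sd(draws)) / sd(draws), 0.1)
  }
})

test_that("WAIC matches quadrature on a conjugate Bernoulli-Beta toy", {
  y <- c(rep(1, 7), rep(0, 3))
  a <- 1 + sum(y); b <- 1 + sum(1 - y)
  # quadrature oracle for lppd and the pointwise variances
  lik <- function(p, yi) if (yi == 1) p else 1 - p
  lppd_q <- vapply(y, function(yi) log(integrate(function(p)
    dbeta(p, a, b) * lik(p, yi), 0, 1)$value), numeric(1))
  var_q <- vapply(y, function(yi) {
    m1 <- integrate(function(p) dbeta(p, a, b) * log(lik(p, yi)), 0, 1)$value
    m2 <- integrate(function(p) dbeta(p, a, b) * log(lik(p, yi))^2, 0, 1)$value
    m2 - m1^2
  }, numeric(1))
  waic_q <- -2 * (sum(lppd_q) - sum(var_q))
  set.seed(21)
  p <- rbeta(4e4, a, b)
  ll <- sapply(y, function(yi) log(lik(p, yi)))
  expect_lt(abs(waic(ll)$waic - waic_q), 0.1)
})

test_that("model spec validation enforces interaction hierarchy", {
  expect_error(survival_model_spec(fixed = c("age", "age_bodymass")),
               "main effects")
  expect_error(survival_model_spec(fixed = c("biomass", "age_biomass")),
               "main effects")
  sp <- survival_model_spec(fixed = c("age", "bodymass", "age_bodymass"))
  expect_s3_class(sp, "survival_model_spec")
  expect_error(mcmc_settings(iterations = 2, thin = 5), "retained")
})

test_that("seeded survival fits are reproducible and permutation invariant", {
  h <- sim_histories(31, c(intercept = 2.3, biomass = 0.7, bodymass = 0.4,
                           hatch = -0.3, age = 0.1, age_bodymass = 0.5),
                     n_broods = 12)
  sp <- survival_model_spec(random = "brood")
  f1 <- suppressWarnings(fit_survival_mcmc(h, sp, quick_mcmc(3)))
  f2 <- suppressWarnings(fit_survival_mcmc(h, sp, quick_mcmc(3)))
  expect_equal(f1$summary$mean, f2$summary$mean, tolerance = 1e-12)
  # permuting interval order leaves the posterior distribution unchanged
  # (up to Monte Carlo error with matched settings)
  hp <- h[rev(seq_len(nrow(h))), ]
  attr(hp, "scaling") <- attr(h, "scaling")
  class(hp) <- class(h)
  f3 <- suppressWarnings(fit_survival_mcmc(hp, sp, quick_mcmc(3)))
  i1 <- f1$summary$parameter == "beta_biomass"
  expect_lt(abs(f1$summary$mean[i1] - f3$summary$mean[i1]),
            4 * (f1$summary$sd[i1] / sqrt(f1$summary$n_eff[i1]) +
                 f3$summary$sd[i1] / sqrt(f3$summary$n_eff[i1])) + 0.05)
  # WAIC comparison of a fit with itself is an exact tie
  cmp <- compare_waic(f1, f2)
  expect_equal(cmp$delta, 0, tolerance = 1e-9)
})

test_that("annual fledging rates are exposure-weighted and delta-extrapolated", {
  h <- sim_histories(13, c(intercept = qlogis(0.93), biomass = 0, bodymass = 0,
                           hatch = 0, age = 0, age_bodymass = 0),
                     n_broods = 20)
  fit <- suppressWarnings(fit_survival_mcmc(
    h, survival_model_spec(fixed = character(0), random = character(0)),
    quick_mcmc(13)))
  ann <- annual_fledging_rates(fit)
  expect_equal(nrow(ann), 4)
  expect_true(all(abs(ann$dsr - 0.93) < 0.03))
  expect_equal(ann$fledging, ann$dsr^21, tolerance = 1e-9)
  expect_equal(ann$fledging_se, 21 * ann$dsr^20 * ann$dsr_se, tolerance = 1e-9)
})
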