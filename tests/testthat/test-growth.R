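test_that("logistic curve and its inverse are mutual inverses on (0, A0)", {
  expect_equal(logistic_mass(12, K = 0.18, Ti = 12), 249 / 2)
  expect_equal(logistic_mass(1e6, K = 0.18, Ti = 12), 249)
  ages <- seq(0, 25, by = 0.5)
  m <- logistic_mass(ages, K = 0.2, Ti = 10)
  expect_true(all(diff(m) > 0))
  back <- estimate_age_from_mass(m, K = 0.2, Ti = 10)
  expect_true(all(abs(back - ages) <= 0.5 + 1e-9))
  expect_equal(estimate_age_from_mass(249 / 2, K = 0.2, Ti = 10), 10)
  expect_error(estimate_age_from_mass(260, K = 0.2, Ti = 10), "asymptote")
  expect_error(estimate_age_from_mass(0, K = 0.2, Ti = 10), "asymptote")
})

test_that("conditional AIC reduces to ordinary AIC at zero random-effect variance", {
  set.seed(3)
  x <- rnorm(40)
  y <- 1 + 2 * x + rnorm(40, 0, 0.5)
  f <- lm(y ~ x)
  X <- cbind(1, x)
  Z <- stats::model.matrix(~factor(rep(1:8, each = 5)) - 1)
  sigma_mle <- sqrt(sum(residuals(f)^2) / 40)
  ca <- phenomatch:::conditional_aic(y, fitted(f), sigma_mle, X, Z, sd_b = 0)
  expect_equal(ca$caic, AIC(f), tolerance = 1e-6)
  expect_equal(ca$rho, 2)
  # with positive random-effect variance the effective df exceed p
  ca2 <- phenomatch:::conditional_aic(y, fitted(f), sigma_mle, X, Z, sd_b = 0.5)
  expect_gt(ca2$rho, 2)
  expect_lt(ca2$rho, 2 + ncol(Z))
})

test_that("growth fitting recovers noise-free parameters and per-year structures", {
  m <- sim_mass_captures(1, n = 60)
  m$mass_g <- logistic_mass(m$age, 0.18, 12)  # strip the noise
  gs <- suppressWarnings(fit_growth_models(m, max_starts = 20))
  expect_lt(abs(gs$top$K_fixed[1] - 0.18), 1e-4)
  expect_lt(abs(gs$top$Ti_fixed[1] - 12), 1e-4)
  # annual Ti offsets are recovered year by year
  m2 <- sim_mass_captures(2, n = 120, Ti_offsets = c(-3, 0, 3), noise = 2)
  gs2 <- suppressWarnings(fit_growth_models(m2, max_starts = 20))
  top <- gs2$top
  expect_equal(top$Ti_structure, "annual")
  expect_equal(unname(top$Ti_fixed[c("2009", "2011")] - top$Ti_fixed["2010"]),
               c(-3, 3), tolerance = 1)
})

test_that("body condition index is the observed/predicted gain ratio", {
  fit <- structure(list(K_structure = "constant", Ti_structure = "constant",
                        A0 = 249, K_fixed = c(`2009` = 0.18),
                        Ti_fixed = c(`2009` = 12), K_indiv = numeric(0),
                        sd_K = 0, sigma = 1, logLik = NA, cAIC = NA,
                        edf = NA, caic_type = "conditional", engine = "nls",
                        n = 0), class = "growth_fit")
  pred_gain <- logistic_mass(8, 0.18, 12) - logistic_mass(4, 0.18, 12)
  masses <- data.frame(chick_id = "a", year = 2009, age = c(4, 8),
                       mass_g = c(50, 50 + 1.2 * pred_gain))
  bci <- compute_bci(masses, fit)
  expect_equal(bci$bci, 1.2, tolerance = 1e-9)
  # a chick growing exactly on the fitted curve has BCI 1 at every recapture
  ages <- c(0, 5, 9, 14, 20)
  on_curve <- data.frame(chick_id = "b", year = 2009, age = ages,
                         mass_g = logistic_mass(ages, 0.18, 12))
  expect_equal(compute_bci(on_curve, fit)$bci, rep(1, 4), tolerance = 1e-9)
  # BCI is scale-free: doubling masses and the asymptote changes nothing
  fit2 <- fit; fit2$A0 <- 498
  on2 <- on_curve; on2$mass_g <- 2 * on2$mass_g
  expect_equal(compute_bci(on2, fit2)$bci, rep(1, 4), tolerance = 1e-9)
})

test_that("BCI additive model recovers a known biomass effect", {
  set.seed(11)
  days <- 140:195
  series <- toy_series(2009, days, 150 + 80 * sin((days - 140) / 8),
                       bodymass = 1.5 + 0.01 * (days - 140))
  n <- 120
  d <- data.frame(chick_id = sprintf("c%03d", 1:n), year = 2009,
                  age1 = 3, age2 = sample(5:20, n, TRUE),
                  observed_gain_g = NA, predicted_gain_g = NA,
                  day = sample(150:190, n, TRUE),
                  hatch_day = sample(145:160, n, TRUE))
  bio7 <- vapply(seq_len(n), function(i)
    rolling_mean(series, 2009, d$day[i], 7), numeric(1))
  d$bci <- 1 + 0.003 * bio7 + rnorm(n, 0, 0.05)
  class(d) <- c("bci_records", "data.frame")
  m <- suppressWarnings(fit_bci_model(d, series))
  expect_equal(m$timescale, 7)
  est <- m$coefficients[m$coefficients$term == "biomass", ]
  expect_gt(est$estimate, 0)
  expect_lt(abs(est$estimate - 0.003), 2 * est$se)
  # the pure-noise covariate (hatch) has no reliably non-zero averaged effect
  hatch <- m$coefficients[m$coefficients$term == "hatch", ]
  if (nrow(hatch) == 1) expect_lt(abs(hatch$estimate), 2 * hatch$se)
})
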