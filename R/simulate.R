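# Synthetic study generator: seasonal invertebrate captures, chick growth
# trajectories, and radio-relocation histories with known ground truth.

# internal: evaluate an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration for the synthetic study generator
#'
#' Defines the simulated study conditions: seven breeding seasons with a
#' unimodal (Gaussian-in-day, optionally skewed) seasonal invertebrate
#' biomass whose peak date and height vary among years; order-specific
#' lognormal body-length distributions matching the observed assemblage
#' composition; per-chick logistic growth with a fixed 249-g asymptote and
#' individual variation in the growth coefficient; and daily survival
#' driven by a known logit-linear model with an age x prey-size
#' interaction, observed through 3-day relocation intervals with
#' right-censoring at 21 days. The default survival coefficients are
#' arbitrary round values picked so that roughly a fifth of chicks fledge
#' (the magnitude of observed shorebird fledging rates); they are not
#' estimates from any data set.
#'
#' @param years Integer vector of season years.
#' @param season_start,season_end Day-of-year bounds of sampling.
#' @param n_transects Number of invertebrate transects (replicates).
#' @param resource_peak_day,resource_peak_height Per-year peak day-of-year
#'   and peak biomass (mg transect^-1 day^-1); recycled to `length(years)`.
#' @param resource_width Gaussian width of the seasonal bump (days);
#'   recycled per year.
#' @param resource_skew Skew-normal shape of the bump (0 = symmetric);
#'   recycled per year, so the direction of the resource tail can differ
#'   among years.
#' @param order_mix Named proportions of taxonomic orders (sum to 1).
#' @param length_meanlog,length_sdlog Named per-order lognormal parameters
#'   of body length (log-mm); names must cover `names(order_mix)`.
#' @param length_season_trend Linear drift of the per-order log length
#'   with day, relative to the year's peak day (log-mm per day): positive
#'   values make prey larger as the season advances, giving the prey-size
#'   covariate a real seasonal signal. The Poisson count intensity is
#'   compensated day by day so the expected biomass curve keeps its
#'   Gaussian shape and peak date.
#' @param length_peak_boost Bump-shaped boost of the per-order log length
#'   (log-mm at the year's peak day, decaying with the same Gaussian
#'   kernel as the biomass bump): prey run largest around the seasonal
#'   pulse. Combines additively with `length_season_trend`; intensity is
#'   compensated so the expected biomass curve is unchanged.
#' @param larval_fraction Fraction of records that are larvae.
#' @param n_broods Broods per year (recycled).
#' @param prob_two_chicks Probability a brood contributes two radio chicks.
#' @param hatch_mean Per-year mean hatch day-of-year (recycled); default
#'   five days before the resource peak.
#' @param hatch_sd SD of hatch dates (days); recycled per year, so
#'   brood synchrony can differ among years.
#' @param growth_K,growth_Ti,A0 Logistic growth parameters (1/day, days, g).
#' @param K_indiv_sd SD of individual deviations on `K`.
#' @param mass_obs_sd Mass measurement noise (g).
#' @param recapture_interval Days between mass recaptures.
#' @param beta Named survival coefficients on the logit scale over
#'   standardized covariates: `intercept`, `biomass`, `bodymass`, `hatch`,
#'   `age`, `age_bodymass`.
#' @param relocation_interval Days between relocation attempts.
#' @param fledge_age Censoring age (days).
#' @param seed Integer master seed; each generator stage draws from its
#'   own stream derived from it by a fixed offset.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(years = c(2009:2011, 2014:2016, 2019),
                       season_start = 135, season_end = 200,
                       n_transects = 2,
                       resource_peak_day = c(165, 170, 161, 174, 159, 172, 166),
                       resource_peak_height = c(320, 260, 300, 180, 150, 240, 280),
                       resource_width = 12,
                       resource_skew = 0,
                       order_mix = c(Araneae = 0.205, Hymenoptera = 0.184,
                                     Coleoptera = 0.175, Diptera = 0.162,
                                     Acari = 0.113, Hemiptera = 0.077,
                                     Collembola = 0.083, Trichoptera = 0.001),
                       length_meanlog = c(Araneae = log(3.2), Hymenoptera = log(2.8),
                                          Coleoptera = log(3.5), Diptera = log(3.0),
                                          Acari = log(1.2), Hemiptera = log(2.6),
                                          Collembola = log(1.5), Trichoptera = log(4)),
                       length_sdlog = c(Araneae = 0.45, Hymenoptera = 0.40,
                                        Coleoptera = 0.45, Diptera = 0.40,
                                        Acari = 0.35, Hemiptera = 0.40,
                                        Collembola = 0.35, Trichoptera = 0.35),
                       length_season_trend = 0.01,
                       length_peak_boost = 0,
                       larval_fraction = 0.12,
                       n_broods = 12, prob_two_chicks = 0.3,
                       hatch_mean = 161, hatch_sd = 4,
                       growth_K = 0.18, growth_Ti = 12, A0 = 249,
                       K_indiv_sd = 0.015, mass_obs_sd = 3,
                       recapture_interval = 6,
                       beta = c(intercept = 2.2, biomass = 0.8, bodymass = 0.5,
                                hatch = -0.3, age = 0, age_bodymass = 0.6),
                       relocation_interval = 3, fledge_age = 21,
                       seed = 1) {
  ny <- length(years)
  resource_peak_day <- rep_len(resource_peak_day, ny)
  resource_peak_height <- rep_len(resource_peak_height, ny)
  n_broods <- rep_len(n_broods, ny)
  if (is.null(hatch_mean)) hatch_mean <- resource_peak_day - 5
  hatch_mean <- rep_len(hatch_mean, ny)
  hatch_sd <- rep_len(hatch_sd, ny)

  if (abs(sum(order_mix) - 1) > 1e-9) stop("order_mix must sum to 1")
  if (any(order_mix < 0)) stop("order_mix proportions must be >= 0")
  stopifnot(all(names(order_mix) %in% names(length_meanlog)),
            all(names(order_mix) %in% names(length_sdlog)))
  resource_width <- rep_len(resource_width, ny)
  resource_skew <- rep_len(resource_skew, ny)
  if (any(hatch_sd < 0) || K_indiv_sd < 0 || mass_obs_sd < 0 || any(resource_width <= 0))
    stop("dispersion parameters must be non-negative (width positive)")
  if (season_start >= season_end) stop("season_start must precede season_end")
  if (fledge_age <= 0) stop("fledge_age must be positive")
  stopifnot(all(c("intercept", "biomass", "bodymass", "hatch", "age",
                  "age_bodymass") %in% names(beta)))
  structure(list(years = years, season_start = season_start,
                 season_end = season_end, n_transects = n_transects,
                 resource_peak_day = setNames(resource_peak_day, years),
                 resource_peak_height = setNames(resource_peak_height, years),
                 resource_width = setNames(resource_width, years),
                 resource_skew = setNames(resource_skew, years),
                 order_mix = order_mix, length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 length_season_trend = length_season_trend,
                 length_peak_boost = length_peak_boost,
                 larval_fraction = larval_fraction,
                 n_broods = setNames(n_broods, years),
                 prob_two_chicks = prob_two_chicks,
                 hatch_mean = setNames(hatch_mean, years),
                 hatch_sd = setNames(hatch_sd, years),
                 growth_K = growth_K, growth_Ti = growth_Ti, A0 = A0,
                 K_indiv_sd = K_indiv_sd, mass_obs_sd = mass_obs_sd,
                 recapture_interval = recapture_interval, beta = beta,
                 relocation_interval = relocation_interval,
                 fledge_age = fledge_age, seed = as.integer(seed)),
            class = "sim_config")
}

# internal: expected filtered (adult, 1.5-9 mm, non-Collembola) dry mass
# per generated record, from truncated lognormal moments of a*L^b
expected_prey_mass_per_record <- function(config, shift = 0,
                                          allometry = default_allometry(),
                                          min_length = 1.5, max_length = 9,
                                          exclude_orders = "Collembola") {
  total <- 0
  for (o in names(config$order_mix)) {
    if (o %in% exclude_orders) next
    mu <- config$length_meanlog[o] + shift; sg <- config$length_sdlog[o]
    row <- match(o, allometry$order)
    if (is.na(row)) row <- match("all", allometry$order)
    a <- allometry$a[row]; b <- allometry$b[row]
    # E[L^b 1{A<=L<=B}] for lognormal L
    mom <- exp(b * mu + b^2 * sg^2 / 2) *
      (pnorm((log(max_length) - mu - b * sg^2) / sg) -
       pnorm((log(min_length) - mu - b * sg^2) / sg))
    total <- total + config$order_mix[o] * (1 - config$larval_fraction) * a * mom
  }
  unname(total)
}

# internal: seasonal intensity kernel (peak value 1 at the mode when skew = 0)
season_kernel <- function(day, peak, width, skew = 0) {
  g <- exp(-(day - peak)^2 / (2 * width^2))
  if (skew != 0) g <- g * 2 * pnorm(skew * (day - peak) / width)
  g
}

#' Simulate invertebrate capture records
#'
#' Draws per-day, per-transect Poisson counts with seasonal intensity
#' proportional to a (optionally skewed) Gaussian bump centred on the
#' year's peak day, calibrated so the expected filtered daily biomass at
#' the peak equals `resource_peak_height`. Each record receives an order
#' (from `order_mix`), a life stage (larva with probability
#' `larval_fraction`), and a body length drawn from the order's lognormal
#' distribution, rounded to the nearest 0.5 mm as in the field protocol.
#' Trap type is pitfall through 2012 and malaise from 2014 on.
#'
#' @param config A [sim_config()].
#' @return Data.frame of invertebrate records: `year`, `day`, `transect`,
#'   `trap_type`, `order`, `life_stage`, `length_mm`.
#' @export
simulate_resources <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  orders <- names(config$order_mix)
  trend <- config$length_season_trend
  boost <- config$length_peak_boost
  with_seed(config$seed + 1L, {
    out <- list()
    for (y in config$years) {
      yc <- as.character(y)
      days <- config$season_start:config$season_end
      # day-specific expected record mass compensates the length trend so
      # the expected filtered biomass stays a Gaussian bump of the stated
      # height and peak date
      g_d <- season_kernel(days, config$resource_peak_day[yc],
                           config$resource_width[yc], config$resource_skew[yc])
      shift_d <- trend * (days - config$resource_peak_day[yc]) + boost * g_d
      M_d <- vapply(shift_d, function(sh) expected_prey_mass_per_record(
        config, shift = sh), numeric(1))
      lam <- config$resource_peak_height[yc] * g_d / M_d
      for (tr in seq_len(config$n_transects)) {
        n <- rpois(length(days), lam)
        if (sum(n) == 0) next
        day <- rep(days, n)
        ord <- sample(orders, sum(n), replace = TRUE, prob = config$order_mix)
        len <- rlnorm(sum(n),
                      config$length_meanlog[ord] +
                        rep(shift_d, n),
                      config$length_sdlog[ord])
        len <- pmax(round(len * 2) / 2, 0.5)
        stage <- ifelse(runif(sum(n)) < config$larval_fraction, "larva", "adult")
        out[[length(out) + 1]] <- data.frame(
          year = y, day = day, transect = paste0("T", tr),
          trap_type = if (y <= 2012) "pitfall" else "malaise",
          order = ord, life_stage = stage, length_mm = len)
      }
    }
    if (length(out) == 0) {
      return(data.frame(year = integer(), day = integer(), transect = character(),
                        trap_type = character(), order = character(),
                        life_stage = character(), length_mm = numeric()))
    }
    res <- do.call(rbind, out)
    res[order(res$year, res$day, res$transect), ][, , drop = FALSE]
  })
}

#' All (year, day) combinations sampled under a simulation configuration
#'
#' The simulated field protocol runs traps every day of the season, so a
#' day with no records is a zero catch; pass this to [aggregate_daily()]
#' as `sampled_days`.
#'
#' @param config A [sim_config()].
#' @return Data.frame with `year` and `day`.
#' @export
sim_sampled_days <- function(config) {
  expand.grid(day = config$season_start:config$season_end,
              year = config$years)[, c("year", "day")]
}

# internal: trailing-window covariate with widening fallback for the
# generator (a missing sampled day must not abort a simulation)
sim_covariate <- function(series, year, day, var, window = 3) {
  v <- rolling_mean(series, year, day, window, var)
  if (!is.finite(v)) v <- rolling_mean(series, year, day, 7, var)
  if (!is.finite(v)) {
    v <- if (var == "biomass_mg") 0 else
      median(series$median_bodymass_mg[series$year == year], na.rm = TRUE)
  }
  v
}

#' Simulate chick broods, growth captures and radio relocations
#'
#' Each brood receives a hatch date and one or two radio-tagged chicks;
#' each chick carries an individual deviation on the logistic growth
#' coefficient and a latent daily mass trajectory. Survival is drawn day
#' by day from the logit-linear model in `config$beta` applied to the
#' day's 3-day trailing resource covariates (standardized internally;
#' constants stored in the truth object). Relocations are emitted every
#' `relocation_interval` days; a death is observed as "dead" at the next
#' scheduled relocation, and chicks alive at `fledge_age` are censored as
#' fledged. Mass captures occur at hatch and on recapture days while the
#' chick is alive.
#'
#' @param config A [sim_config()].
#' @param series A `daily_resource_series` spanning all hatch dates plus
#'   the fledging age (typically `aggregate_daily(filter_potential_prey(
#'   simulate_resources(config)))`).
#' @return List: `chicks`, `masses`, `relocations` (data.frames) and
#'   `truth` (betas, standardization constants, per-chick death ages,
#'   growth deviations).
#' @export
simulate_chicks <- function(config, series) {
  stopifnot(inherits(config, "sim_config"))
  need <- config$hatch_mean + config$fledge_age
  if (max(need) > config$season_end + 14) {
    stop("resource series season cannot span hatch dates + fledge age")
  }
  # precompute per-day 3-day trailing covariates for all season days
  cov <- list()
  for (y in config$years) {
    days <- config$season_start:config$season_end
    cov[[as.character(y)]] <- data.frame(
      day = days,
      bio = vapply(days, function(d) sim_covariate(series, y, d, "biomass_mg"),
                   numeric(1)),
      bm = vapply(days, function(d) sim_covariate(series, y, d,
                                                  "median_bodymass_mg"),
                  numeric(1)))
  }
  allbio <- unlist(lapply(cov, `[[`, "bio"))
  allbm <- unlist(lapply(cov, `[[`, "bm"))
  sc <- list(center = c(biomass = mean(allbio), bodymass = mean(allbm),
                        hatch = NA_real_, age = NA_real_),
             scale = c(biomass = 2 * sd(allbio), bodymass = 2 * sd(allbm),
                       hatch = NA_real_, age = NA_real_))
  ages_grid <- 0:(config$fledge_age - 1)
  sc$center["age"] <- mean(ages_grid); sc$scale["age"] <- 2 * sd(ages_grid)

  with_seed(config$seed + 2L, {
    chicks <- list(); truth_rows <- list()
    cid <- 0
    for (y in config$years) {
      yc <- as.character(y)
      for (b in seq_len(config$n_broods[yc])) {
        hatch <- round(rnorm(1, config$hatch_mean[yc], config$hatch_sd[yc]))
        hatch <- min(max(hatch, config$season_start + 3),
                     config$season_end - config$fledge_age)
        nch <- 1 + rbinom(1, 1, config$prob_two_chicks)
        for (k in seq_len(nch)) {
          cid <- cid + 1
          chicks[[cid]] <- data.frame(
            chick_id = sprintf("C%04d", cid),
            brood_id = sprintf("B%d_%02d", y, b),
            plot = if (b %% 2 == 0) "North" else "South",
            year = y, hatch_day = hatch,
            K_dev = rnorm(1, 0, config$K_indiv_sd))
        }
      }
    }
    if (length(chicks) == 0) {
      empty_chicks <- data.frame(chick_id = character(), brood_id = character(),
                                 plot = character(), year = integer(),
                                 hatch_day = integer())
      return(list(chicks = empty_chicks,
                  masses = data.frame(chick_id = character(), year = integer(),
                                      day = integer(), age = numeric(),
                                      mass_g = numeric(), hatch_day = integer()),
                  relocations = data.frame(chick_id = character(),
                                           year = integer(), day = integer(),
                                           status = character()),
                  truth = list(beta = config$beta, scaling = sc,
                               growth_K = config$growth_K,
                               growth_Ti = config$growth_Ti, A0 = config$A0,
                               chicks = empty_chicks)))
    }
    chicks <- do.call(rbind, chicks)
    hatch_all <- chicks$hatch_day
    sc$center["hatch"] <- mean(hatch_all)
    sc$scale["hatch"] <- max(2 * sd(hatch_all), 1e-9)

    bsim <- config$beta
    masses <- list(); relocs <- list()
    for (i in seq_len(nrow(chicks))) {
      y <- chicks$year[i]; yc <- as.character(y)
      hatch <- chicks$hatch_day[i]
      K <- config$growth_K + chicks$K_dev[i]
      z_h <- (hatch - sc$center["hatch"]) / sc$scale["hatch"]
      death_age <- NA_real_
      for (a in 0:(config$fledge_age - 1)) {
        d <- hatch + a
        cd <- cov[[yc]]
        z_bio <- (cd$bio[cd$day == d] - sc$center["biomass"]) / sc$scale["biomass"]
        z_bm <- (cd$bm[cd$day == d] - sc$center["bodymass"]) / sc$scale["bodymass"]
        z_a <- (a - sc$center["age"]) / sc$scale["age"]
        eta <- bsim["intercept"] + bsim["biomass"] * z_bio +
          bsim["bodymass"] * z_bm + bsim["hatch"] * z_h +
          bsim["age"] * z_a + bsim["age_bodymass"] * z_a * z_bm
        if (runif(1) > plogis(eta)) { death_age <- a + 1; break }
      }
      fledged <- is.na(death_age)
      last_age <- if (fledged) config$fledge_age else death_age

      # relocations every relocation_interval days; death seen at the next one
      rel_ages <- seq(config$relocation_interval, config$fledge_age,
                      by = config$relocation_interval)
      if (!config$fledge_age %in% rel_ages) rel_ages <- c(rel_ages, config$fledge_age)
      rr <- list()
      for (ra in rel_ages) {
        if (!fledged && ra >= death_age) {
          rr[[length(rr) + 1]] <- data.frame(chick_id = chicks$chick_id[i],
                                             year = y, day = hatch + ra,
                                             status = "dead")
          break
        }
        rr[[length(rr) + 1]] <- data.frame(chick_id = chicks$chick_id[i],
                                           year = y, day = hatch + ra,
                                           status = "alive")
      }
      relocs[[length(relocs) + 1]] <- do.call(rbind, rr)

      # mass captures: hatch plus irregular recaptures while alive
      cap_ages <- seq(config$recapture_interval, config$fledge_age,
                      by = config$recapture_interval)
      cap_ages <- c(0, pmax(cap_ages + sample(-1:1, length(cap_ages),
                                              replace = TRUE), 1))
      cap_ages <- cap_ages[cap_ages < last_age | (fledged & cap_ages <= last_age)]
      mm <- logistic_mass(cap_ages, K, config$growth_Ti, config$A0) +
        rnorm(length(cap_ages), 0, config$mass_obs_sd)
      masses[[length(masses) + 1]] <- data.frame(
        chick_id = chicks$chick_id[i], year = y, day = hatch + cap_ages,
        age = cap_ages, mass_g = pmax(mm, 1), hatch_day = hatch)
      truth_rows[[i]] <- data.frame(chick_id = chicks$chick_id[i],
                                    death_age = death_age, fledged = fledged)
    }
    truth <- list(beta = bsim, scaling = sc,
                  growth_K = config$growth_K, growth_Ti = config$growth_Ti,
                  A0 = config$A0,
                  chicks = merge(chicks, do.call(rbind, truth_rows),
                                 by = "chick_id"))
    list(chicks = chicks[, c("chick_id", "brood_id", "plot", "year", "hatch_day")],
         masses = do.call(rbind, masses),
         relocations = do.call(rbind, relocs),
         truth = truth)
  })
}

#' Write a complete synthetic fixture set to disk
#'
#' Generates resources and chicks from a configuration and writes the four
#' CSVs in the documented schemas (ISO-8601 dates) plus a ground-truth
#' JSON file.
#'
#' @param config A [sim_config()].
#' @param outdir Writable directory (created if needed).
#' @return Named character vector of the file paths written.
#' @export
write_fixture_set <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  inv <- simulate_resources(config)
  # the simulated protocol runs traps every season day
  series <- aggregate_daily(filter_potential_prey(inv),
                            sampled_days = sim_sampled_days(config))
  ch <- simulate_chicks(config, series)
  iso <- function(year, day) {
    if (length(day) == 0) return(character(0))
    as.character(as.Date(day - 1, origin = paste0(year, "-01-01")))
  }
  paths <- c(invertebrates = file.path(outdir, "invertebrates.csv"),
             chicks = file.path(outdir, "chicks.csv"),
             masses = file.path(outdir, "masses.csv"),
             relocations = file.path(outdir, "relocations.csv"),
             truth = file.path(outdir, "truth.json"))
  write.csv(data.frame(date = iso(inv$year, inv$day), transect = inv$transect,
                       trap_type = inv$trap_type, order = inv$order,
                       life_stage = inv$life_stage, length_mm = inv$length_mm),
            paths["invertebrates"], row.names = FALSE)
  write.csv(data.frame(chick_id = ch$chicks$chick_id,
                       brood_id = ch$chicks$brood_id, plot = ch$chicks$plot,
                       hatch_date = iso(ch$chicks$year, ch$chicks$hatch_day)),
            paths["chicks"], row.names = FALSE)
  write.csv(data.frame(chick_id = ch$masses$chick_id,
                       date = iso(ch$masses$year, ch$masses$day),
                       mass_g = round(ch$masses$mass_g, 1)),
            paths["masses"], row.names = FALSE)
  write.csv(data.frame(chick_id = ch$relocations$chick_id,
                       date = iso(ch$relocations$year, ch$relocations$day),
                       status = ch$relocations$status),
            paths["relocations"], row.names = FALSE)
  tr <- ch$truth
  jsonlite::write_json(
    list(beta = as.list(tr$beta),
         scaling = list(center = as.list(tr$scaling$center),
                        scale = as.list(tr$scaling$scale)),
         growth_K = tr$growth_K, growth_Ti = tr$growth_Ti, A0 = tr$A0,
         chicks = tr$chicks, seed = config$seed),
    paths["truth"], auto_unbox = TRUE, digits = NA, na = "null")
  paths
}
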