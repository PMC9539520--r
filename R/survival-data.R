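#' Build known-fate encounter histories from relocation records
#'
#' Converts per-chick radio-relocation records into interval-censored
#' encounter histories for the daily-survival model. Intervals are cut at
#' the dates of live relocations (hatch counts as a live contact at age 0).
#' A confirmed carcass ends the history with a `died_within` interval from
#' the last live contact; so does a run of `gap_days` (default 3)
#' consecutive days without relocating the chick, with the death interval
#' ending on the last day of the run. Chicks alive at `fledge_age`
#' (default 21 days, the radio lifespan) are right-censored as fledged.
#' Chicks flagged in an optional logical `exclude` column of `chicks`
#' (human-caused mortality, day-0 radio loss) are dropped and counted.
#'
#' Interval covariates follow the relocation cadence: daily invertebrate
#' biomass and median body mass are trailing `window`-day means (default 3,
#' the relocation interval) anchored on the interval's end day; hatch date
#' is the chick's hatch day-of-year; age is the interval midpoint.
#' Standardized copies (Gelman scaling: centred, divided by two SDs) are
#' stored alongside the raw values; supply `scaling` to reuse fixed
#' centres/scales (e.g. from a simulation's ground truth).
#'
#' @param chicks Data.frame: `chick_id`, `brood_id`, `plot`, `year`,
#'   `hatch_day` (day-of-year), optional logical `exclude`.
#' @param relocations Data.frame: `chick_id`, `day` (day-of-year),
#'   `status` in `{"alive", "dead", "missing"}`.
#' @param series A `daily_resource_series` covering all occupied days.
#' @param fledge_age Age at which survivors are censored as fledged.
#' @param gap_days Consecutive missing days treated as death.
#' @param window Trailing window (days) for the resource covariates.
#' @param scaling Optional named list with `center` and `scale` vectors
#'   over `c("biomass", "bodymass", "hatch", "age")`.
#' @return A data.frame of class `encounter_histories`, one row per
#'   interval: ids, `start_age`, `end_age`, `len`, `fate`
#'   (`survived`/`died_within`/`censored`), raw and `z_`-prefixed
#'   covariates. Attributes: `scaling`, `excluded`, `fledge_age`.
#' @export
build_encounter_histories <- function(chicks, relocations, series,
                                      fledge_age = 21, gap_days = 3,
                                      window = 3, scaling = NULL) {
  stopifnot(all(c("chick_id", "brood_id", "plot", "year", "hatch_day") %in% names(chicks)))
  stopifnot(all(c("chick_id", "day", "status") %in% names(relocations)))
  bad <- setdiff(unique(relocations$chick_id), chicks$chick_id)
  if (length(bad)) stop("relocations reference unknown chick(s): ",
                        paste(head(bad, 5), collapse = ", "))
  excluded <- character(0)
  if ("exclude" %in% names(chicks)) {
    excluded <- as.character(chicks$chick_id[isTRUE_vec(chicks$exclude)])
  }
  rows <- list()
  for (i in seq_len(nrow(chicks))) {
    id <- chicks$chick_id[i]
    if (as.character(id) %in% excluded) next
    hd <- chicks$hatch_day[i]
    rel <- relocations[relocations$chick_id == id, , drop = FALSE]
    rel <- rel[order(rel$day), , drop = FALSE]
    if (nrow(rel) == 0) next
    age <- rel$day - hd
    if (any(age < 0)) stop("relocation before hatch for chick ", id)

    # death: confirmed carcass, or >= gap_days consecutive missing days
    death_age <- NA_real_
    dead_idx <- which(rel$status == "dead")
    if (length(dead_idx)) death_age <- age[dead_idx[1]]
    miss <- which(rel$status == "missing")
    if (length(miss) >= gap_days) {
      md <- rel$day[miss]
      run <- 1
      for (j in seq_along(md)[-1]) {
        run <- if (md[j] - md[j - 1] == 1) run + 1 else 1
        if (run >= gap_days) {
          cand <- md[j] - hd
          if (is.na(death_age) || cand < death_age) death_age <- cand
          break
        }
      }
    }

    alive_ages <- age[rel$status == "alive"]
    if (!is.na(death_age)) alive_ages <- alive_ages[alive_ages < death_age]
    bounds <- sort(unique(c(0, alive_ages)))
    fates <- NULL; sa <- NULL; ea <- NULL
    if (length(bounds) > 1) {
      sa <- bounds[-length(bounds)]; ea <- bounds[-1]
      fates <- rep("survived", length(sa))
    }
    if (!is.na(death_age) && death_age <= fledge_age) {
      la <- max(bounds)
      if (death_age > la) {
        sa <- c(sa, la); ea <- c(ea, death_age); fates <- c(fates, "died_within")
      }
    }
    if (length(sa) == 0) next
    # censor at fledge_age
    keep <- sa < fledge_age
    sa <- sa[keep]; ea <- ea[keep]; fates <- fates[keep]
    if (length(sa) == 0) next
    over <- ea >= fledge_age
    ea[over] <- fledge_age
    fates[over & fates == "survived"] <- "censored"
    if (any(fates == "died_within")) {
      di <- which(fates == "died_within")
      if (di[1] < length(fates)) { # death must be terminal
        sa <- sa[1:di[1]]; ea <- ea[1:di[1]]; fates <- fates[1:di[1]]
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      chick_id = id, brood_id = chicks$brood_id[i], plot = chicks$plot[i],
      year = chicks$year[i], hatch_day = hd,
      start_age = sa, end_age = ea, len = ea - sa, fate = fates)
  }
  if (length(rows) == 0) stop("no usable encounter histories")
  h <- do.call(rbind, rows)
  rownames(h) <- NULL

  # interval covariates anchored on the interval's last exposure day
  # (ages start..end-1 are the days survived), so a 3-day window matches
  # a 3-day interval exactly; the prey-size signal is slow-moving, so a
  # window with no prey catch falls back to a 7-day window, then the
  # year median
  h$biomass <- NA_real_; h$bodymass <- NA_real_
  for (j in seq_len(nrow(h))) {
    ed <- h$hatch_day[j] + h$end_age[j] - 1
    h$biomass[j] <- rolling_mean(series, h$year[j], ed, window, "biomass_mg")
    bm <- rolling_mean(series, h$year[j], ed, window, "median_bodymass_mg")
    if (!is.finite(bm)) bm <- rolling_mean(series, h$year[j], ed, 7,
                                           "median_bodymass_mg")
    if (!is.finite(bm)) bm <- median(series$median_bodymass_mg[series$year == h$year[j]],
                                     na.rm = TRUE)
    h$bodymass[j] <- bm
  }
  if (anyNA(h$biomass) || anyNA(h$bodymass)) {
    miss <- unique(h$chick_id[is.na(h$biomass) | is.na(h$bodymass)])
    stop("resource covariate missing for occupied day(s) of chick(s): ",
         paste(head(miss, 5), collapse = ", "))
  }
  h$hatch <- h$hatch_day
  h$age <- (h$start_age + h$end_age) / 2

  vars <- c("biomass", "bodymass", "hatch", "age")
  if (is.null(scaling)) {
    scaling <- list(center = numeric(0), scale = numeric(0))
    for (v in vars) {
      if (length(unique(h[[v]])) < 2) {
        # degenerate covariate (e.g. a single chick): centre only
        h[[paste0("z_", v)]] <- h[[v]] - h[[v]][1]
        scaling$center[v] <- h[[v]][1]
        scaling$scale[v] <- 1
        next
      }
      z <- standardize_gelman(h[[v]])
      h[[paste0("z_", v)]] <- as.numeric(z)
      scaling$center[v] <- attr(z, "center")
      scaling$scale[v] <- attr(z, "scale")
    }
  } else {
    for (v in vars) {
      h[[paste0("z_", v)]] <- (h[[v]] - scaling$center[v]) / scaling$scale[v]
    }
  }
  attr(h, "scaling") <- scaling
  attr(h, "excluded") <- excluded
  attr(h, "fledge_age") <- fledge_age
  class(h) <- c("encounter_histories", "data.frame")
  h
}

# internal: NA-safe logical test, vectorized
isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.encounter_histories <- function(x, ...) {
  nch <- length(unique(x$chick_id))
  cat("Encounter histories:", nch, "chicks,", nrow(x), "intervals;",
      sum(x$fate == "died_within"), "deaths,",
      sum(x$fate == "censored"), "censored (fledged)\n")
  ex <- attr(x, "excluded")
  if (length(ex)) cat("  excluded chicks:", length(ex), "\n")
  invisible(x)
}

#' Known-fate interval log-likelihood
#'
#' Log-likelihood contribution of one chick's encounter history given a
#' daily survival probability for every occupied day, in history order.
#' A survived (or censored) interval contributes the sum of `log(s_d)`
#' over its days; a `died_within` interval contributes
#' `log(1 - prod(s_d))` over its days (the chick died on some unknown day
#' of the interval).
#'
#' @param history Data.frame with columns `len` (days) and `fate`; rows in
#'   chronological order, at most one terminal `died_within`.
#' @param daily_survival Numeric vector of per-day survival probabilities,
#'   strictly inside (0, 1), of length `sum(history$len)`.
#' @return The log-likelihood (scalar).
#' @export
#' @examples
#' h <- data.frame(len = 3, fate = "survived")
#' interval_log_likelihood(h, rep(0.9, 3))  # log(0.9^3)
interval_log_likelihood <- function(history, daily_survival) {
  stopifnot(all(c("len", "fate") %in% names(history)))
  if (any(daily_survival <= 0) || any(daily_survival >= 1)) {
    stop("daily survival probabilities must lie strictly in (0, 1)")
  }
  if (length(daily_survival) != sum(history$len)) {
    stop("need one survival probability per occupied day (",
         sum(history$len), "), got ", length(daily_survival))
  }
  idx <- rep(seq_len(nrow(history)), history$len)
  ll <- 0
  for (i in seq_len(nrow(history))) {
    s <- daily_survival[idx == i]
    ll <- ll + if (history$fate[i] == "died_within") log(1 - prod(s)) else sum(log(s))
  }
  ll
}
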