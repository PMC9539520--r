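#' Filter invertebrate records to potential chick prey
#'
#' Precocial shorebird chicks are gape-limited surface foragers: they take
#' adult invertebrates in a restricted size band and rarely consume larvae.
#' This filter keeps adult records with body lengths in a closed interval
#' (default 1.5-9 mm) and drops excluded orders (default Collembola, which
#' are primarily aquatic and infrequent prey). Record order is preserved.
#'
#' @param records Data.frame of invertebrate records with at least columns
#'   `life_stage` ("adult"/"larva"), `order`, `length_mm`.
#' @param min_length,max_length Closed length bounds in mm.
#' @param exclude_orders Character vector of orders to drop.
#' @return The filtered data.frame (possibly zero rows), same columns.
#' @export
filter_potential_prey <- function(records, min_length = 1.5, max_length = 9,
                                  exclude_orders = "Collembola") {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) return(records)
  stopifnot(all(c("life_stage", "order", "length_mm") %in% names(records)))
  keep <- records$life_stage == "adult" &
    records$length_mm >= min_length &
    records$length_mm <= max_length &
    !(records$order %in% exclude_orders)
  records[keep, , drop = FALSE]
}

#' Aggregate prey records into a daily resource series
#'
#' Computes, for every sampled (year, day), the inferred daily biomass
#' (mg transect^-1 day^-1) and the daily median per-capita dry mass (mg).
#' Transects are treated as replicates: each transect's record masses are
#' summed and the biomass is the mean of those sums over the transects
#' that reported records that day. Days where only a subset of transects
#' reported are averaged over the reporting transects (trap failure is not
#' distinguishable from a zero catch in the schema); `n_transects` exposes
#' the coverage so such days can be audited.
#'
#' @param records Filtered prey records with columns `year`, `day`
#'   (day-of-year), `transect`, `order`, `length_mm`.
#' @param allometry Length-mass table, see [default_allometry()].
#' @param sampled_days Optional data.frame with `year` and `day` listing
#'   every day traps were run (typically the unique days of the
#'   unfiltered records). Sampled days with no prey records then enter
#'   the series with zero biomass (and missing median body mass) instead
#'   of being absent, distinguishing a zero catch from a day not sampled.
#' @return A data.frame of class `daily_resource_series` with columns
#'   `year`, `day`, `biomass_mg`, `median_bodymass_mg`, `n_records`,
#'   `n_transects`, sorted by year then day.
#' @export
aggregate_daily <- function(records, allometry = default_allometry(),
                            sampled_days = NULL) {
  stopifnot(is.data.frame(records))
  cols <- c("year", "day", "transect", "order", "length_mm")
  stopifnot(all(cols %in% names(records)))
  rows <- list()
  if (nrow(records) > 0) {
    mass <- length_to_dry_mass(records$length_mm, records$order, allometry)
    key <- interaction(records$year, records$day, drop = TRUE)
    split_idx <- split(seq_len(nrow(records)), key)
    rows <- lapply(split_idx, function(ii) {
      m <- mass[ii]
      tsum <- tapply(m, records$transect[ii], sum)
      data.frame(year = records$year[ii][1], day = records$day[ii][1],
                 biomass_mg = mean(tsum),
                 median_bodymass_mg = median(m),
                 n_records = length(ii),
                 n_transects = length(tsum))
    })
  }
  out <- do.call(rbind, rows)
  if (!is.null(sampled_days)) {
    sampled_days <- unique(sampled_days[, c("year", "day")])
    have <- if (is.null(out)) character(0) else paste(out$year, out$day)
    zero <- sampled_days[!(paste(sampled_days$year, sampled_days$day) %in% have), ,
                         drop = FALSE]
    if (nrow(zero) > 0) {
      out <- rbind(out, data.frame(year = zero$year, day = zero$day,
                                   biomass_mg = 0,
                                   median_bodymass_mg = NA_real_,
                                   n_records = 0L, n_transects = 0L))
    }
  }
  if (is.null(out)) {
    out <- data.frame(year = integer(), day = integer(), biomass_mg = numeric(),
                      median_bodymass_mg = numeric(), n_records = integer(),
                      n_transects = integer())
    class(out) <- c("daily_resource_series", "data.frame")
    return(out)
  }
  out <- out[order(out$year, out$day), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("daily_resource_series", "data.frame")
  out
}

#' @export
print.daily_resource_series <- function(x, ...) {
  cat("Daily resource series:", length(unique(x$year)), "season(s),",
      nrow(x), "sampled days\n")
  if (nrow(x) > 0) {
    cat(sprintf("  biomass %.1f-%.1f mg/transect/day; median body mass %.2f-%.2f mg\n",
                min(x$biomass_mg), max(x$biomass_mg),
                min(x$median_bodymass_mg, na.rm = TRUE),
                max(x$median_bodymass_mg, na.rm = TRUE)))
  }
  invisible(x)
}

#' Trailing rolling mean of a daily series variable
#'
#' Mean of the available daily values in the window of `window` days ending
#' at (and including) `anchor_day`. Days missing from the series are simply
#' absent from the mean (no interpolation); a window containing no sampled
#' day yields `NA`. `window = 1` returns the day's own value and
#' `window = 0` is accepted as a synonym for "day-of".
#'
#' @param series A `daily_resource_series` (or any data.frame with `year`,
#'   `day` and the requested variable).
#' @param year Season year.
#' @param anchor_day Day-of-year at which the window ends.
#' @param window Window length in days (typically 1, 3 or 7).
#' @param var Variable to average, default `"biomass_mg"`.
#' @return A single numeric value (NA if no data fall in the window).
#' @export
rolling_mean <- function(series, year, anchor_day, window = 3,
                         var = "biomass_mg") {
  stopifnot(var %in% names(series), length(anchor_day) == 1)
  if (window <= 0) window <- 1
  lo <- anchor_day - window + 1
  sel <- series$year == year & series$day >= lo & series$day <= anchor_day
  v <- series[[var]][sel]
  v <- v[is.finite(v)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

# internal: quadratic vertex of value ~ day + day^2 by OLS; window = NULL
# fits the whole series, otherwise only days within `window` of the argmax
# (a local fit that stays concave for skewed or spiky curves)
quad_vertex <- function(day, value, window = NULL) {
  if (!is.null(window)) {
    keep <- abs(day - day[which.max(value)]) <= window
    day <- day[keep]; value <- value[keep]
  }
  if (length(unique(day)) < 3) stop("need >= 3 distinct days for a quadratic fit")
  fit <- lm(value ~ day + I(day^2))
  b <- coef(fit)
  if (!is.finite(b[3]) || b[3] >= 0) stop("no interior maximum: quadratic coefficient is not negative")
  list(peak_day = unname(-b[2] / (2 * b[3])), coef = unname(b))
}

#' Estimate the seasonal peak date by a quadratic fit
#'
#' Fits `biomass ~ day + day^2` by ordinary least squares within one season
#' and returns the vertex `-b1/(2 b2)` as the peak date, the standard
#' derivative-zero estimator for unimodal seasonal abundance.
#'
#' @param series A `daily_resource_series`.
#' @param year Season to fit.
#' @param var Response column, default `"biomass_mg"`.
#' @return A list of class `peak_estimate`: `year`, `peak_day`, `coef`
#'   (intercept, day, day^2).
#' @export
fit_quadratic_peak <- function(series, year, var = "biomass_mg") {
  sel <- series$year == year
  if (!any(sel)) stop("no data for year ", year)
  v <- quad_vertex(series$day[sel], series[[var]][sel])
  structure(list(year = year, peak_day = v$peak_day, coef = v$coef),
            class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat(sprintf("Quadratic peak, %s: day %.1f\n", x$year, x$peak_day))
  invisible(x)
}

#' Standardize a vector by centring and dividing by two standard deviations
#'
#' Gelman's scaling for regression inputs: `(x - mean(x)) / (2 sd(x))`,
#' giving the output mean 0 and standard deviation 0.5 so that coefficients
#' of continuous and binary inputs are comparable.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return The standardized vector, with attributes `center` and `scale`
#'   (`scale` = 2 sd).
#' @export
#' @examples
#' standardize_gelman(c(1, 2, 3))
standardize_gelman <- function(x) {
  x <- as.numeric(x)
  if (length(unique(x[is.finite(x)])) < 2) stop("standardize_gelman: need >= 2 distinct values")
  m <- mean(x, na.rm = TRUE)
  s <- 2 * sd(x, na.rm = TRUE)
  structure((x - m) / s, center = m, scale = s)
}

#' Interannual linear trend from a mixed-effect model
#'
#' Fits a linear mixed model of a response on year with the requested
#' random intercepts (restricted maximum likelihood via \pkg{lme4}).
#' Response and year are standardized internally (Gelman scaling) and the
#' slope is back-transformed to original response units per year. Marginal
#' and conditional R2 follow Nakagawa & Schielzeth. A 95% Wald interval
#' excluding zero flags the trend as `relevant`. A singular or failed
#' mixed fit falls back to an ordinary least-squares fit with a warning.
#'
#' @param data Data.frame with a `year` column, the response column, and
#'   any grouping columns named in `random`.
#' @param response Name of the response column.
#' @param random Character vector of grouping columns to use as random
#'   intercepts (columns absent from `data` are dropped silently).
#' @return A list of class `trend_result`: `slope`, `se`, `ci95_low`,
#'   `ci95_high` (original units per year), `marginal_R2`,
#'   `conditional_R2`, `relevant`, `n`, `fallback_lm`.
#' @export
fit_trend <- function(data, response, random = c("trap_type", "sample_date")) {
  stopifnot(is.data.frame(data), response %in% names(data), "year" %in% names(data))
  data <- data[is.finite(data[[response]]) & is.finite(data$year), , drop = FALSE]
  if (length(unique(data$year)) < 2) stop("fit_trend: need >= 2 years")
  y_z <- standardize_gelman(data[[response]])
  x_z <- standardize_gelman(data$year)
  sy <- attr(y_z, "scale"); sx <- attr(x_z, "scale")
  d <- data.frame(.y = as.numeric(y_z), .x = as.numeric(x_z))
  random <- intersect(random, names(data))
  random <- random[vapply(random, function(r) length(unique(data[[r]])) > 1, logical(1))]
  for (r in random) d[[r]] <- factor(data[[r]])

  fallback <- FALSE
  fit <- NULL
  if (length(random) > 0) {
    fml <- as.formula(paste(".y ~ .x +",
                            paste(sprintf("(1 | %s)", random), collapse = " + ")))
    fit <- tryCatch(
      suppressMessages(lme4::lmer(fml, data = d, REML = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-5)) {
      # keep the fit only if the singular component is not the whole structure
      vc <- as.data.frame(lme4::VarCorr(fit))
      if (all(vc$vcov[vc$grp != "Residual"] < 1e-10)) fit <- NULL
    }
  }
  if (is.null(fit)) {
    if (length(random) > 0) warning("fit_trend: singular or failed mixed fit; falling back to fixed effects only")
    fallback <- TRUE
    lmfit <- lm(.y ~ .x, data = d)
    slope_z <- coef(lmfit)[".x"]
    se_z <- sqrt(vcov(lmfit)[".x", ".x"])
    r2 <- summary(lmfit)$r.squared
    r2m <- r2; r2c <- r2
  } else {
    slope_z <- lme4::fixef(fit)[".x"]
    se_z <- sqrt(vcov(fit)[".x", ".x"])
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_re <- sum(vc$vcov[vc$grp != "Residual"])
    var_res <- vc$vcov[vc$grp == "Residual"]
    var_fix <- var(as.numeric(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
    r2m <- var_fix / (var_fix + var_re + var_res)
    r2c <- (var_fix + var_re) / (var_fix + var_re + var_res)
  }
  scale_back <- sy / sx
  slope <- unname(slope_z) * scale_back
  se <- unname(se_z) * scale_back
  ci <- slope + c(-1, 1) * qnorm(0.975) * se
  structure(list(slope = slope, se = se,
                 ci95_low = ci[1], ci95_high = ci[2],
                 marginal_R2 = unname(r2m), conditional_R2 = unname(r2c),
                 relevant = ci[1] > 0 || ci[2] < 0,
                 n = nrow(d), fallback_lm = fallback),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Trend: %.4g +/- %.4g per year (95%% CI %.4g, %.4g)%s\n",
              x$slope, x$se, x$ci95_low, x$ci95_high,
              if (x$relevant) " [CI excludes 0]" else ""))
  cat(sprintf("  R2 marginal %.3f, conditional %.3f; n = %d%s\n",
              x$marginal_R2, x$conditional_R2, x$n,
              if (x$fallback_lm) " (fixed-effects fallback)" else ""))
  invisible(x)
}

#' Seasonal span helper: years eligible for peak estimation
#'
#' Seasons sampled for fewer than `min_span` days (shortened field seasons)
#' are excluded from annual peak-timing analyses, while remaining available
#' for daily biomass and body-mass trends.
#'
#' @param series A `daily_resource_series`.
#' @param min_span Minimum sampled span (last day - first day + 1), default 30.
#' @return Integer vector of eligible years.
#' @export
peak_eligible_years <- function(series, min_span = 30) {
  yrs <- unique(series$year)
  ok <- vapply(yrs, function(y) {
    d <- series$day[series$year == y]
    diff(range(d)) + 1 >= min_span
  }, logical(1))
  yrs[ok]
}
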