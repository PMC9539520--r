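#' Annual resource phenology curve
#'
#' Daily proportions of the season's invertebrate biomass: each sampled
#' day's biomass divided by the annual sum, so the curve sums to 1 and is
#' invariant to rescaling the biomass.
#'
#' @param series A `daily_resource_series`.
#' @param year Season year.
#' @return A data.frame of class `phenology_curve` with columns `year`,
#'   `day`, `proportion`; attribute `mode = "resource"`.
#' @export
resource_curve <- function(series, year) {
  sel <- series$year == year
  if (!any(sel)) stop("no data for year ", year)
  b <- series$biomass_mg[sel]
  if (all(b <= 0)) stop("all-zero biomass in ", year, ": no resource curve")
  out <- data.frame(year = year, day = series$day[sel], proportion = b / sum(b))
  out <- out[order(out$day), ]
  rownames(out) <- NULL
  attr(out, "mode") <- "resource"
  class(out) <- c("phenology_curve", "data.frame")
  out
}

# internal: normalize a day/weight table into a phenology_curve
as_phenology_curve <- function(year, day, weight, mode) {
  if (sum(weight) <= 0) stop("empty demand curve for ", year)
  agg <- tapply(weight, day, sum)
  out <- data.frame(year = year, day = as.numeric(names(agg)),
                    proportion = as.numeric(agg) / sum(agg))
  out <- out[order(out$day), ]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  class(out) <- c("phenology_curve", "data.frame")
  out
}

#' Chick occupancy schedule from encounter histories
#'
#' Reduces encounter histories to one row per chick: hatch day and the
#' last age the chick contributes demand. Fledged (censored) chicks
#' contribute through the fledging age; chicks with an interval-censored
#' death contribute through the midpoint of their death interval; chicks
#' whose radio contact simply ended contribute through their last contact.
#'
#' @param histories An `encounter_histories` object (or a data.frame with
#'   `chick_id`, `year`, `hatch_day`, `start_age`, `end_age`, `fate`).
#' @return Data.frame: `chick_id`, `year`, `hatch_day`, `end_age`.
#' @export
chick_schedule <- function(histories) {
  stopifnot(all(c("chick_id", "year", "hatch_day", "start_age", "end_age",
                  "fate") %in% names(histories)))
  out <- lapply(split(histories, histories$chick_id), function(h) {
    last <- h[which.max(h$end_age), ]
    end <- if (last$fate == "died_within")
      (last$start_age + last$end_age) / 2 else last$end_age
    data.frame(chick_id = last$chick_id, year = last$year,
               hatch_day = last$hatch_day, end_age = end)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Peak-demand consumer phenology curve
#'
#' The conventional single-timepoint consumer curve: each chick still
#' alive at the age of peak growth rate (the growth-curve inflection
#' `Ti`) contributes one unit of demand on the calendar day
#' `hatch + Ti`; the curve is the normalized daily frequency of those
#' dates. Chicks dying before `Ti` contribute nothing.
#'
#' @param schedule Chick schedule (see [chick_schedule()]), or an
#'   `encounter_histories` object.
#' @param fit A `growth_fit` supplying the (year-specific) inflection.
#' @param year Season year.
#' @return A `phenology_curve` with attribute `mode = "peak_demand"`.
#' @export
peak_demand_curve <- function(schedule, fit, year) {
  if (inherits(schedule, "encounter_histories")) schedule <- chick_schedule(schedule)
  s <- schedule[schedule$year == year, , drop = FALSE]
  if (nrow(s) == 0) stop("no chicks in ", year)
  Ti <- growth_params(fit, year)$Ti
  s <- s[s$end_age >= Ti, , drop = FALSE]
  if (nrow(s) == 0) stop("no chicks alive at the inflection age in ", year)
  as_phenology_curve(year, s$hatch_day + round(Ti), rep(1, nrow(s)),
                     "peak_demand")
}

#' Whole-demand consumer phenology curve
#'
#' Age-structured consumer phenology: on every calendar day, total demand
#' is the sum over chicks alive that day of their predicted mass raised to
#' the demand exponent `theta` (metabolic allometry; `theta = 1` gives
#' mass-proportional demand, `theta = 0` a daily head count). The curve is
#' normalized to daily proportions.
#'
#' @param schedule Chick schedule or `encounter_histories`.
#' @param fit A `growth_fit`.
#' @param year Season year.
#' @param theta Demand exponent (> = 0), default 0.75.
#' @return A `phenology_curve` with attribute `mode = "whole_demand"` and
#'   attribute `theta`.
#' @export
whole_demand_curve <- function(schedule, fit, year, theta = 0.75) {
  stopifnot(theta >= 0)
  if (inherits(schedule, "encounter_histories")) schedule <- chick_schedule(schedule)
  s <- schedule[schedule$year == year, , drop = FALSE]
  if (nrow(s) == 0) stop("no chicks in ", year)
  days <- c(); wt <- c()
  for (i in seq_len(nrow(s))) {
    ages <- seq(0, floor(s$end_age[i]))
    m <- predict_mass(fit, ages, year = year)
    days <- c(days, s$hatch_day[i] + ages)
    wt <- c(wt, m^theta)
  }
  out <- as_phenology_curve(year, days, wt, "whole_demand")
  attr(out, "theta") <- theta
  out
}

#' Proportional-overlap index of two phenology curves
#'
#' The shared area of two daily-proportion curves: the sum over days of
#' the pointwise minimum of the two proportions. Days absent from one
#' curve count as zero there. The index is symmetric, lies in [0, 1],
#' and equals 1 only for identical curves.
#'
#' @param consumer,resource `phenology_curve` objects for the same year.
#' @return Overlap proportion in [0, 1].
#' @export
overlap_index <- function(consumer, resource) {
  if (consumer$year[1] != resource$year[1]) {
    stop("curves are from different years (", consumer$year[1], " vs ",
         resource$year[1], ")")
  }
  days <- sort(union(consumer$day, resource$day))
  pc <- setNames(rep(0, length(days)), days)
  pr <- pc
  pc[as.character(consumer$day)] <- consumer$proportion
  pr[as.character(resource$day)] <- resource$proportion
  sum(pmin(pc, pr))
}

#' Cumulative seasonal resource availability (curve height)
#'
#' Area under the unnormalized daily biomass curve over the season, with
#' each sampled day contributing a unit-day-width bar: the sum of daily
#' biomass values, in mg.
#'
#' @param series A `daily_resource_series`.
#' @param year Season year.
#' @return Curve height in mg (0 for an all-zero or empty season).
#' @export
curve_height <- function(series, year) {
  sel <- series$year == year
  sum(series$biomass_mg[sel])
}

#' Difference in peak dates between resource and demand curves
#'
#' Both curves are fit with the quadratic derivative-zero peak estimator;
#' the synchrony measure is the resource peak day minus the demand peak
#' day (positive when resources peak later than demand). With
#' `local_window` set, each quadratic is fit only to days within that
#' distance of the curve's maximum, which keeps the fit concave for
#' skewed or narrow curves; the default fits each full curve.
#'
#' @param series A `daily_resource_series` (resource side).
#' @param demand A `phenology_curve` (demand side).
#' @param year Season year.
#' @param local_window Optional half-width (days) of a local fit window
#'   around each curve's maximum.
#' @return Difference in days.
#' @export
peak_date_difference <- function(series, demand, year, local_window = NULL) {
  sel <- series$year == year
  if (!any(sel)) stop("no data for year ", year)
  rp <- quad_vertex(series$day[sel], series$biomass_mg[sel], local_window)$peak_day
  dp <- quad_vertex(demand$day, demand$proportion, local_window)$peak_day
  rp - dp
}

#' Compute the four annual mismatch metrics
#'
#' For each requested year: overlap of the resource curve with the
#' whole-demand and peak-demand curves, the difference in peak dates
#' (resource minus peak-demand curve), and the curve height.
#'
#' @param series A `daily_resource_series`.
#' @param histories `encounter_histories` (or a chick schedule).
#' @param fit A `growth_fit`.
#' @param years Years to process (default: years present in both inputs).
#' @param theta Demand exponent for the whole-demand curve.
#' @return Data.frame of class `mismatch_metrics`: `year`,
#'   `overlap_whole`, `overlap_peak`, `peak_diff_days`, `curve_height`.
#'   Years where a curve cannot be built get NA with a warning.
#' @export
mismatch_metrics <- function(series, histories, fit, years = NULL,
                             theta = 0.75) {
  sched <- if (inherits(histories, "encounter_histories"))
    chick_schedule(histories) else histories
  if (is.null(years)) years <- intersect(unique(series$year), unique(sched$year))
  out <- lapply(sort(years), function(y) {
    row <- data.frame(year = y, overlap_whole = NA_real_,
                      overlap_peak = NA_real_, peak_diff_days = NA_real_,
                      curve_height = curve_height(series, y))
    tryCatch({
      rc <- resource_curve(series, y)
      wd <- whole_demand_curve(sched, fit, y, theta)
      pd <- peak_demand_curve(sched, fit, y)
      row$overlap_whole <- overlap_index(wd, rc)
      row$overlap_peak <- overlap_index(pd, rc)
      # local windows bound both vertex fits near their maxima; a year
      # whose narrow demand histogram still admits no interior maximum
      # keeps an undefined dates metric for that year
      row$peak_diff_days <- peak_date_difference(series, pd, y,
                                                 local_window = 12)
    }, error = function(e) warning("year ", y, ": ", conditionMessage(e)))
    row
  })
  res <- do.call(rbind, out)
  class(res) <- c("mismatch_metrics", "data.frame")
  res
}

#' Relate annual mismatch metrics to fledging rates
#'
#' Four univariate ordinary least-squares models of the annual fledging
#' rate on each mismatch metric, compared by small-sample AIC: per model
#' the slope and SE, adjusted R2, AICc, and Akaike weight over the model
#' set.
#'
#' @param metrics A `mismatch_metrics` data.frame.
#' @param fledging Data.frame with `year` and `fledging` (rate in [0, 1]);
#'   e.g. from [annual_fledging_rates()]. Years missing from either input
#'   are dropped.
#' @param metrics_vars Metric columns to use as predictors.
#' @return Data.frame of class `annual_model_table`: `metric`, `slope`,
#'   `se`, `adj_R2`, `AICc`, `delta`, `weight`, ranked by AICc.
#' @export
fit_annual_models <- function(metrics, fledging,
                              metrics_vars = c("overlap_whole", "overlap_peak",
                                               "peak_diff_days", "curve_height")) {
  d <- merge(metrics, fledging[, c("year", "fledging")], by = "year")
  # a metric defined in too few years drops from the comparison rather
  # than starving the remaining models of their common years
  enough <- vapply(metrics_vars, function(v)
    sum(is.finite(d[[v]]) & is.finite(d$fledging)) >= 4, logical(1))
  if (any(!enough)) {
    warning("metric(s) dropped (defined in < 4 years): ",
            paste(metrics_vars[!enough], collapse = ", "))
    metrics_vars <- metrics_vars[enough]
  }
  if (length(metrics_vars) == 0) stop("no metric is defined in >= 4 years")
  d <- d[complete.cases(d[, c(metrics_vars, "fledging")]), , drop = FALSE]
  if (nrow(d) < 4) stop("need >= 4 years with both metrics and fledging rates")
  rows <- lapply(metrics_vars, function(v) {
    f <- lm(as.formula(paste("fledging ~", v)), data = d)
    k <- 3  # slope, intercept, residual variance
    n <- nrow(d)
    aicc <- AIC(f) + 2 * k * (k + 1) / max(n - k - 1, 1)
    data.frame(metric = v, slope = coef(f)[2],
               se = sqrt(vcov(f)[2, 2]),
               adj_R2 = summary(f)$adj.r.squared, AICc = aicc)
  })
  tab <- do.call(rbind, rows)
  tab$delta <- tab$AICc - min(tab$AICc)
  tab$weight <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  tab <- tab[order(tab$AICc), ]
  rownames(tab) <- NULL
  attr(tab, "n_years") <- nrow(d)
  class(tab) <- c("annual_model_table", "data.frame")
  tab
}

#' @export
print.annual_model_table <- function(x, ...) {
  cat("Annual fledging-rate models (", attr(x, "n_years"), " years):\n", sep = "")
  print(cbind(x["metric"], round(as.data.frame(x)[-1], 3)), row.names = FALSE)
  invisible(x)
}
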