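# Schema-validated readers and the end-to-end pipeline runner.

# internal: read a CSV and check required columns
read_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("[read] ", what, " file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss)) stop("[read] ", what, " file ", path,
                         " is missing column(s): ", paste(miss, collapse = ", "))
  d
}

# internal: parse ISO dates into year + day-of-year, reporting bad rows
parse_iso <- function(x, what) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d) | is.na(x))
  if (length(bad)) stop("[read] malformed date(s) in ", what, " at row(s): ",
                        paste(head(bad, 5), collapse = ", "))
  list(year = as.integer(format(d, "%Y")), day = as.integer(format(d, "%j")))
}

#' Read an invertebrate records CSV
#'
#' Schema: `date` (ISO-8601), `transect`, `trap_type`, `order`,
#' `life_stage`, `length_mm`.
#'
#' @param path CSV path.
#' @return Data.frame with `year` and `day` (day-of-year) added.
#' @export
read_invertebrates <- function(path) {
  d <- read_checked(path, c("date", "transect", "trap_type", "order",
                            "life_stage", "length_mm"), "invertebrates")
  p <- parse_iso(d$date, "invertebrates")
  d$year <- p$year; d$day <- p$day
  if (any(!is.finite(d$length_mm) | d$length_mm <= 0)) {
    stop("[read] non-positive length_mm at row(s): ",
         paste(head(which(!is.finite(d$length_mm) | d$length_mm <= 0), 5),
               collapse = ", "))
  }
  d
}

#' Read a chicks CSV
#'
#' Schema: `chick_id`, `brood_id`, `plot`, `hatch_date` (ISO-8601);
#' optional logical `exclude`.
#'
#' @param path CSV path.
#' @return Data.frame with `year` and `hatch_day` added.
#' @export
read_chicks <- function(path) {
  d <- read_checked(path, c("chick_id", "brood_id", "plot", "hatch_date"),
                    "chicks")
  if (nrow(d)) {
    p <- parse_iso(d$hatch_date, "chicks")
    d$year <- p$year; d$hatch_day <- p$day
  } else { d$year <- integer(0); d$hatch_day <- integer(0) }
  if (anyDuplicated(d$chick_id)) stop("[read] duplicated chick_id in ", path)
  d
}

#' Read a mass-captures CSV
#'
#' Schema: `chick_id`, `date` (ISO-8601), `mass_g`.
#'
#' @param path CSV path.
#' @param chicks Chick table from [read_chicks()], used to derive ages.
#' @return Data.frame with `year`, `day`, `age`, `hatch_day` added.
#' @export
read_masses <- function(path, chicks = NULL) {
  d <- read_checked(path, c("chick_id", "date", "mass_g"), "masses")
  if (nrow(d)) {
    p <- parse_iso(d$date, "masses")
    d$year <- p$year; d$day <- p$day
  } else { d$year <- integer(0); d$day <- integer(0) }
  if (!is.null(chicks) && nrow(d)) {
    idx <- match(d$chick_id, chicks$chick_id)
    if (anyNA(idx)) stop("[read] masses reference unknown chick(s): ",
                         paste(head(unique(d$chick_id[is.na(idx)]), 5),
                               collapse = ", "))
    d$hatch_day <- chicks$hatch_day[idx]
    d$age <- d$day - d$hatch_day
  }
  d
}

#' Read a relocations CSV
#'
#' Schema: `chick_id`, `date` (ISO-8601), `status` in
#' `{"alive", "dead", "missing"}`.
#'
#' @param path CSV path.
#' @return Data.frame with `year` and `day` added.
#' @export
read_relocations <- function(path) {
  d <- read_checked(path, c("chick_id", "date", "status"), "relocations")
  if (nrow(d)) {
    p <- parse_iso(d$date, "relocations")
    d$year <- p$year; d$day <- p$day
  } else { d$year <- integer(0); d$day <- integer(0) }
  bad <- which(!d$status %in% c("alive", "dead", "missing"))
  if (length(bad)) stop("[read] invalid status at row(s): ",
                        paste(head(bad, 5), collapse = ", "))
  d
}

#' Pipeline configuration
#'
#' Bundles input paths and analysis settings for [run_pipeline()].
#'
#' @param invertebrates,chicks,masses,relocations Input CSV paths (see the
#'   reader functions for schemas). Alternatively give `fixture_dir`, a
#'   directory containing the four default-named files.
#' @param fixture_dir Optional directory of fixture CSVs.
#' @param allometry Allometry table (data.frame) or CSV path with columns
#'   `order`, `a`, `b`.
#' @param min_length,max_length Prey length filter bounds (mm).
#' @param fledge_age Censoring age (days).
#' @param gap_days Consecutive missing days treated as death.
#' @param window Trailing covariate window (days).
#' @param theta Whole-demand exponent.
#' @param mcmc An [mcmc_settings()].
#' @param seed Master seed (overrides `mcmc$seed`).
#' @param outdir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(invertebrates = NULL, chicks = NULL, masses = NULL,
                            relocations = NULL, fixture_dir = NULL,
                            allometry = default_allometry(),
                            min_length = 1.5, max_length = 9,
                            fledge_age = 21, gap_days = 3, window = 3,
                            theta = 0.75, mcmc = mcmc_settings(),
                            seed = 1, outdir = tempfile("phenomatch_run_")) {
  if (!is.null(fixture_dir)) {
    invertebrates <- file.path(fixture_dir, "invertebrates.csv")
    chicks <- file.path(fixture_dir, "chicks.csv")
    masses <- file.path(fixture_dir, "masses.csv")
    relocations <- file.path(fixture_dir, "relocations.csv")
  }
  if (is.character(allometry)) allometry <- read.csv(allometry)
  stopifnot(min_length > 0, max_length > min_length, fledge_age > 0,
            gap_days > 0, window > 0, theta >= 0)
  mcmc$seed <- as.integer(seed)
  structure(list(invertebrates = invertebrates, chicks = chicks,
                 masses = masses, relocations = relocations,
                 allometry = allometry, min_length = min_length,
                 max_length = max_length, fledge_age = fledge_age,
                 gap_days = gap_days, window = window, theta = theta,
                 mcmc = mcmc, seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

# internal: run one stage with stage-tagged errors
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full mismatch pipeline
#'
#' Executes the four analysis stages in order -- resources (filter,
#' aggregate, trends, peaks), growth (logistic model selection, BCI),
#' survival (Bayesian known-fate MCMC, annual fledging rates), mismatch
#' (curves, the four metrics, the annual model comparison) -- writing all
#' stage outputs as CSVs plus a JSON report. Every stochastic step is
#' driven by `config$seed`, so a run is reproducible from (inputs, config,
#' seed); inputs are never modified.
#'
#' @param config A [pipeline_config()].
#' @return The run report (list, invisibly identical to the JSON written
#'   to `outdir/report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list()

  inv <- stage("read", read_invertebrates(config$invertebrates))
  chk <- stage("read", read_chicks(config$chicks))
  mas <- stage("read", read_masses(config$masses, chk))
  rel <- stage("read", read_relocations(config$relocations))
  log$records_in <- c(invertebrates = nrow(inv), chicks = nrow(chk),
                      masses = nrow(mas), relocations = nrow(rel))

  # --- resources ---
  res <- stage("resources", {
    prey <- filter_potential_prey(inv, config$min_length, config$max_length)
    series <- aggregate_daily(prey, config$allometry,
                              sampled_days = inv[, c("year", "day")])
    elig <- peak_eligible_years(series)
    peaks <- lapply(elig, function(y)
      tryCatch(fit_quadratic_peak(series, y), error = function(e) NULL))
    peaks <- do.call(rbind, lapply(Filter(Negate(is.null), peaks), function(p)
      data.frame(year = p$year, peak_day = p$peak_day)))
    series$trap_type <- ifelse(series$year <= 2012, "pitfall", "malaise")
    # day-of-year as grouping: the same calendar day recurs across years
    series$sample_date <- series$day
    trends <- list(
      biomass = fit_trend(series, "biomass_mg"),
      bodymass = fit_trend(series, "median_bodymass_mg"))
    if (!is.null(peaks) && length(unique(peaks$year)) >= 2) {
      peaks$trap_type <- ifelse(peaks$year <= 2012, "pitfall", "malaise")
      trends$peak_day <- tryCatch(
        fit_trend(peaks, "peak_day", random = "trap_type"),
        error = function(e) NULL)
    }
    list(prey = prey, series = series, peaks = peaks, trends = trends)
  })
  log$prey_records <- nrow(res$prey)
  write.csv(as.data.frame(res$series), file.path(config$outdir, "daily_series.csv"),
            row.names = FALSE)
  if (!is.null(res$peaks)) {
    write.csv(res$peaks, file.path(config$outdir, "peaks.csv"), row.names = FALSE)
  }

  # --- growth ---
  gro <- stage("growth", {
    sel <- fit_growth_models(mas)
    bci <- tryCatch(compute_bci(mas, sel$top), error = function(e) NULL)
    bcim <- if (!is.null(bci))
      tryCatch(fit_bci_model(bci, res$series), error = function(e) NULL)
    list(selection = sel, bci = bci, bci_model = bcim)
  })
  write.csv(gro$selection$table, file.path(config$outdir, "growth_selection.csv"),
            row.names = FALSE)
  if (!is.null(gro$bci)) {
    write.csv(as.data.frame(gro$bci), file.path(config$outdir, "bci.csv"),
              row.names = FALSE)
  }

  # --- survival ---
  sur <- stage("survival", {
    hist <- build_encounter_histories(chk, rel, res$series,
                                      fledge_age = config$fledge_age,
                                      gap_days = config$gap_days,
                                      window = config$window)
    fit <- fit_survival_mcmc(hist, survival_model_spec(), config$mcmc)
    annual <- annual_fledging_rates(fit)
    list(histories = hist, fit = fit, annual = annual)
  })
  write.csv(sur$fit$summary, file.path(config$outdir, "posterior_summary.csv"),
            row.names = FALSE)
  write.csv(sur$annual, file.path(config$outdir, "annual_fledging.csv"),
            row.names = FALSE)
  log$chicks_excluded <- length(attr(sur$histories, "excluded"))

  # --- mismatch ---
  mis <- stage("mismatch", {
    metrics <- mismatch_metrics(res$series, sur$histories, gro$selection$top,
                                theta = config$theta)
    models <- tryCatch(fit_annual_models(metrics, sur$annual),
                       error = function(e) NULL)
    list(metrics = metrics, models = models)
  })
  write.csv(as.data.frame(mis$metrics), file.path(config$outdir, "metrics.csv"),
            row.names = FALSE)
  if (!is.null(mis$models)) {
    write.csv(as.data.frame(mis$models),
              file.path(config$outdir, "annual_models.csv"), row.names = FALSE)
  }

  cfg_hashable <- config
  cfg_hashable$outdir <- NULL
  hf <- tempfile()
  saveRDS(cfg_hashable, hf)
  config_hash <- unname(tools::md5sum(hf))
  unlink(hf)

  report <- list(
    seed = config$seed,
    config_hash = config_hash,
    log = log,
    trends = lapply(res$trends, function(t) if (is.null(t)) NULL else
      t[c("slope", "se", "ci95_low", "ci95_high", "marginal_R2",
          "conditional_R2", "relevant")]),
    growth = list(table = gro$selection$table,
                  top = gro$selection$top[c("K_structure", "Ti_structure",
                                            "K_fixed", "Ti_fixed", "sd_K")]),
    bci = if (!is.null(gro$bci_model))
      list(timescale = gro$bci_model$timescale,
           coefficients = gro$bci_model$coefficients),
    survival = list(summary = sur$fit$summary,
                    n_intervals = nrow(sur$histories),
                    n_chicks = length(unique(sur$histories$chick_id)),
                    converged = sur$fit$converged,
                    waic = sur$fit$waic[c("waic", "se", "p_waic")],
                    annual = sur$annual),
    mismatch = list(metrics = as.data.frame(mis$metrics),
                    models = if (!is.null(mis$models)) as.data.frame(mis$models)))
  rpath <- file.path(config$outdir, "report.json")
  jsonlite::write_json(report, rpath, auto_unbox = TRUE, digits = 10,
                       na = "null", force = TRUE)
  report$report_hash <- unname(tools::md5sum(rpath))
  invisible(report)
}
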