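#' Logistic growth curve with fixed asymptote
#'
#' Predicted body mass at a given age under the logistic growth function
#' `A0 / (1 + exp(-K (age - Ti)))`, with the asymptote `A0` fixed (default
#' 249 g, the mean adult mass of the two sexes pooled), growth coefficient
#' `K` (1/day) and inflection point `Ti` (days). At `age = Ti` the curve
#' passes through `A0/2` and the growth rate is maximal.
#'
#' @param age Age in days (>= 0 for chick work, but any real is accepted).
#' @param K Logistic growth coefficient (1/day).
#' @param Ti Inflection point (days).
#' @param A0 Fixed asymptotic mass (g).
#' @return Predicted mass in g.
#' @export
#' @examples
#' logistic_mass(12, K = 0.18, Ti = 12)  # = 249/2
logistic_mass <- function(age, K, Ti, A0 = 249) {
  A0 / (1 + exp(-K * (age - Ti)))
}

#' Estimate chick age from a mass measurement
#'
#' Inverts the fitted logistic growth curve:
#' `age = Ti - log(A0/mass - 1)/K`, using the year-appropriate `(K, Ti)`
#' from a growth fit, rounded to the nearest half day (field ageing
#' precision). Used to age chicks captured away from the nest.
#'
#' @param mass_g Observed mass in g, must lie strictly in `(0, A0)`.
#' @param fit A `growth_fit` (see [fit_growth_models()]), or `NULL` to use
#'   `K`/`Ti`/`A0` directly.
#' @param year Year for annual parameter structures (ignored for constant).
#' @param K,Ti,A0 Parameters used when `fit` is `NULL`.
#' @return Estimated age in days (multiple of 0.5).
#' @export
estimate_age_from_mass <- function(mass_g, fit = NULL, year = NULL,
                                   K = NULL, Ti = NULL, A0 = 249) {
  if (!is.null(fit)) {
    p <- growth_params(fit, year)
    K <- p$K; Ti <- p$Ti; A0 <- fit$A0
  }
  stopifnot(is.numeric(K), is.numeric(Ti))
  if (any(mass_g <= 0) || any(mass_g >= A0)) {
    stop("mass must lie strictly between 0 and the asymptote A0 = ", A0, " g")
  }
  age <- Ti - log(A0 / mass_g - 1) / K
  round(age * 2) / 2
}

# internal: population-level (K, Ti) for a given year from a growth_fit
growth_params <- function(fit, year = NULL) {
  K <- fit$K_fixed; Ti <- fit$Ti_fixed
  pick <- function(v) {
    if (length(v) == 1 || is.null(year)) return(unname(v[1]))
    nm <- as.character(year)
    if (nm %in% names(v)) unname(v[nm]) else unname(mean(v))
  }
  list(K = pick(K), Ti = pick(Ti))
}

#' Predict mass from a fitted growth model
#'
#' @param fit A `growth_fit`.
#' @param age Ages in days.
#' @param year Optional year (for annual K/Ti structures).
#' @param chick_id Optional chick id; if the chick has an estimated
#'   individual deviation on K it is added.
#' @return Predicted masses in g.
#' @export
predict_mass <- function(fit, age, year = NULL, chick_id = NULL) {
  p <- growth_params(fit, year)
  K <- p$K
  if (!is.null(chick_id) && length(fit$K_indiv) &&
      as.character(chick_id) %in% names(fit$K_indiv)) {
    K <- K + unname(fit$K_indiv[as.character(chick_id)])
  }
  logistic_mass(age, K = K, Ti = p$Ti, A0 = fit$A0)
}

# internal: conditional AIC from the linearized mixed model.
# rho = trace of the hat matrix mapping y to conditional fitted values in
# the working linear model [X Z] with ridge penalty sigma^2/sd_b^2 on the
# random-effect block; cAIC = -2 * conditional logLik + 2 * (rho + 1)
# (the +1 counts the residual variance). With sd_b = 0 this reduces to
# ordinary AIC of the fixed-effects fit.
conditional_aic <- function(y, mu_cond, sigma, X, Z, sd_b) {
  p <- ncol(X)
  cll <- sum(dnorm(y, mu_cond, sigma, log = TRUE))
  if (is.null(Z) || ncol(Z) == 0 || sd_b < 1e-8) {
    rho <- p
  } else {
    C <- cbind(X, Z)
    D <- diag(c(rep(0, p), rep(sigma^2 / sd_b^2, ncol(Z))))
    M <- crossprod(C) + D
    rho <- sum(diag(solve(M, crossprod(C))))
  }
  list(caic = -2 * cll + 2 * (rho + 1), rho = rho, cll = cll)
}

# internal: gradient columns of the logistic curve wrt K and Ti
logistic_grads <- function(age, K, Ti, A0) {
  e <- exp(-K * (age - Ti))
  g <- e / (1 + e)^2
  list(dK = A0 * (age - Ti) * g, dTi = -A0 * K * g)
}

# internal: fit one candidate structure, with jittered restarts
fit_one_growth <- function(masses, K_structure, Ti_structure, A0,
                           start_K, start_Ti, max_starts) {
  d <- data.frame(mass_g = masses$mass_g, age = masses$age,
                  chick_id = factor(masses$chick_id),
                  year_f = factor(masses$year))
  ann_K <- K_structure == "annual"
  ann_Ti <- Ti_structure == "annual"
  nyr <- nlevels(d$year_f)
  if ((ann_K || ann_Ti) && nyr < 2) stop("annual structure needs >= 2 years")
  fixed <- list(
    as.formula(if (ann_K) "K ~ year_f" else "K ~ 1"),
    as.formula(if (ann_Ti) "Ti ~ year_f" else "Ti ~ 1"))
  nK <- if (ann_K) nyr else 1
  nTi <- if (ann_Ti) nyr else 1
  base_start <- c(start_K, rep(0, nK - 1), start_Ti, rep(0, nTi - 1))

  fit <- NULL
  for (it in seq_len(max_starts)) {
    st <- base_start
    if (it > 1) {
      st[1] <- start_K * exp(rnorm(1, 0, 0.25))
      st[nK + 1] <- start_Ti + rnorm(1, 0, 2)
      if (nK > 1) st[2:nK] <- rnorm(nK - 1, 0, 0.02)
      if (nTi > 1) st[(nK + 2):(nK + nTi)] <- rnorm(nTi - 1, 0, 1)
    }
    fit <- tryCatch(
      nlme::nlme(as.formula(sprintf(
                   "mass_g ~ %.10g / (1 + exp(-K * (age - Ti)))", A0)),
                 data = d, fixed = fixed, random = K ~ 1 | chick_id,
                 start = st,
                 control = nlme::nlmeControl(maxIter = 200, msMaxIter = 200,
                                             returnObject = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }

  engine <- "nlme"
  if (is.null(fit)) {
    # fall back to a fixed-effects-only fit (individual variance -> 0)
    engine <- "nls"
    rhs <- paste0(A0, "/(1+exp(-(", if (ann_K) "K[year_i]" else "K", ")*(age-(",
                  if (ann_Ti) "Ti[year_i]" else "Ti", "))))")
    d$year_i <- as.integer(d$year_f)
    st <- list(K = rep(start_K, nK), Ti = rep(start_Ti, nTi))
    if (!ann_K) st$K <- start_K
    if (!ann_Ti) st$Ti <- start_Ti
    fit <- tryCatch(
      minpack.lm::nlsLM(as.formula(paste("mass_g ~", rhs)), data = d, start = st),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
  }

  yrs <- levels(d$year_f)
  if (engine == "nlme") {
    fe <- nlme::fixef(fit)
    Kpar <- fe[grep("^K", names(fe))]
    Tipar <- fe[grep("^Ti", names(fe))]
    expand <- function(par, annual) {
      if (!annual) return(setNames(unname(par[1]), yrs[1]))
      setNames(unname(par[1]) + c(0, unname(par[-1])), yrs)
    }
    K_fixed <- expand(Kpar, ann_K)
    Ti_fixed <- expand(Tipar, ann_Ti)
    re <- nlme::ranef(fit)
    K_indiv <- setNames(re[, 1], rownames(re))
    sd_K <- as.numeric(nlme::VarCorr(fit)[1, "StdDev"])
    sigma <- fit$sigma
    ll <- as.numeric(logLik(fit))
  } else {
    cf <- coef(fit)
    K_fixed <- if (ann_K) setNames(cf[grep("^K", names(cf))], yrs)
               else setNames(unname(cf["K"]), yrs[1])
    Ti_fixed <- if (ann_Ti) setNames(cf[grep("^Ti", names(cf))], yrs)
                else setNames(unname(cf["Ti"]), yrs[1])
    K_indiv <- numeric(0)
    sd_K <- 0
    sigma <- summary(fit)$sigma
    ll <- as.numeric(logLik(fit))
  }
  if (any(K_fixed <= 0)) return(NULL)

  # conditional AIC from the linearization at the estimates
  byyear <- function(v) {
    if (length(v) == 1) rep(unname(v), nrow(d))
    else unname(v[as.character(d$year_f)])
  }
  kdev <- K_indiv[as.character(d$chick_id)]
  kdev[is.na(kdev)] <- 0
  row_K <- byyear(K_fixed) + kdev
  row_Ti <- byyear(Ti_fixed)
  mu_cond <- logistic_mass(d$age, row_K, row_Ti, A0)
  gr <- logistic_grads(d$age, row_K, row_Ti, A0)
  MMK <- if (ann_K) stats::model.matrix(~year_f, d) else matrix(1, nrow(d), 1)
  MMTi <- if (ann_Ti) stats::model.matrix(~year_f, d) else matrix(1, nrow(d), 1)
  X <- cbind(MMK * gr$dK, MMTi * gr$dTi)
  Z <- stats::model.matrix(~chick_id - 1, d) * gr$dK
  caic <- tryCatch(conditional_aic(d$mass_g, mu_cond, sigma, X, Z, sd_K),
                   error = function(e) NULL)
  caic_type <- "conditional"
  if (is.null(caic) || !is.finite(caic$caic)) {
    # unstable linearization: downgrade to marginal small-sample AIC
    warning("conditional AIC unstable; using marginal AICc for structure (",
            K_structure, " K, ", Ti_structure, " Ti)")
    k <- nK + nTi + 1 + (engine == "nlme")
    n <- nrow(d)
    caic <- list(caic = -2 * ll + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1),
                 rho = k, cll = ll)
    caic_type <- "marginal_AICc"
  }

  structure(list(K_structure = K_structure, Ti_structure = Ti_structure,
                 A0 = A0, K_fixed = K_fixed, Ti_fixed = Ti_fixed,
                 K_indiv = K_indiv, sd_K = sd_K, sigma = sigma,
                 logLik = ll, cAIC = caic$caic, edf = caic$rho,
                 caic_type = caic_type, engine = engine, n = nrow(d)),
            class = "growth_fit")
}

#' Fit and rank candidate logistic growth models
#'
#' Fits the four candidate fixed-asymptote logistic growth structures --
#' growth coefficient `K` constant or annual, inflection point `Ti`
#' constant or annual -- each with an individual random intercept on `K`,
#' by nonlinear mixed-effects estimation (\pkg{nlme}) with up to
#' `max_starts` jittered restarts per structure. Candidates are ranked by
#' conditional AIC (effective degrees of freedom from the trace of the
#' linearized hat matrix); structures within `delta_candidate` of the best
#' are flagged as the candidate set. A structure whose mixed fit never
#' converges is refit without the individual term (fixed effects only) and
#' retained with zero random-effect variance.
#'
#' @param masses Data.frame with columns `chick_id`, `year`, `age` (days),
#'   `mass_g`. At least some chicks need two or more captures.
#' @param A0 Fixed asymptote (g), default 249.
#' @param start_K,start_Ti Starting values (site-typical defaults).
#' @param max_starts Maximum jittered restarts per structure (default 100).
#' @param delta_candidate cAIC window for the candidate set (default 4).
#' @return A `growth_selection`: list with `fits` (ranked `growth_fit`s),
#'   `table` (structure, cAIC, delta, candidate flag), `top`.
#' @export
fit_growth_models <- function(masses, A0 = 249, start_K = 0.2, start_Ti = 10,
                              max_starts = 100, delta_candidate = 4) {
  stopifnot(all(c("chick_id", "year", "age", "mass_g") %in% names(masses)))
  masses <- masses[is.finite(masses$age) & is.finite(masses$mass_g), , drop = FALSE]
  if (nrow(masses) < 4) stop("too few mass captures to fit growth models")
  nyr <- length(unique(masses$year))
  grid <- expand.grid(K_structure = c("constant", "annual"),
                      Ti_structure = c("constant", "annual"),
                      stringsAsFactors = FALSE)
  if (nyr < 2) grid <- grid[grid$K_structure == "constant" &
                            grid$Ti_structure == "constant", , drop = FALSE]
  fits <- list()
  for (i in seq_len(nrow(grid))) {
    f <- tryCatch(fit_one_growth(masses, grid$K_structure[i], grid$Ti_structure[i],
                                 A0, start_K, start_Ti, max_starts),
                  error = function(e) NULL)
    if (is.null(f)) {
      warning("growth structure (", grid$K_structure[i], " K, ",
              grid$Ti_structure[i], " Ti) failed to converge; excluded")
    } else {
      fits[[length(fits) + 1]] <- f
    }
  }
  if (length(fits) == 0) stop("no growth model converged")
  ord <- order(vapply(fits, `[[`, numeric(1), "cAIC"))
  fits <- fits[ord]
  caic <- vapply(fits, `[[`, numeric(1), "cAIC")
  tab <- data.frame(
    K_structure = vapply(fits, `[[`, character(1), "K_structure"),
    Ti_structure = vapply(fits, `[[`, character(1), "Ti_structure"),
    engine = vapply(fits, `[[`, character(1), "engine"),
    cAIC = caic, delta = caic - caic[1],
    candidate = caic - caic[1] < delta_candidate)
  structure(list(fits = fits, table = tab, top = fits[[1]]),
            class = "growth_selection")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Logistic growth fit (A0 = %g g fixed): %s K, %s Ti [%s]\n",
              x$A0, x$K_structure, x$Ti_structure, x$engine))
  cat("  K:", paste(sprintf("%s=%.4f", names(x$K_fixed), x$K_fixed), collapse = ", "), "\n")
  cat("  Ti:", paste(sprintf("%s=%.2f", names(x$Ti_fixed), x$Ti_fixed), collapse = ", "), "\n")
  cat(sprintf("  sd(K individual) = %.4g, sigma = %.3g g, cAIC = %.2f (%s)\n",
              x$sd_K, x$sigma, x$cAIC, x$caic_type))
  invisible(x)
}

#' @export
print.growth_selection <- function(x, ...) {
  cat("Growth model selection (ranked by cAIC):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Body condition index at each recapture
#'
#' For every pair of consecutive captures of a chick, the body condition
#' index is the observed mass gain divided by the gain predicted over the
#' same age interval by the population-level curve of the supplied growth
#' fit (year-specific where the fit is annual). BCI = 1 means on-curve
#' growth; above/below 1 means faster/slower than expected.
#'
#' @param masses Data.frame with `chick_id`, `year`, `age`, `mass_g`, and
#'   optionally `day` (day-of-year of capture, carried through) and
#'   `hatch_day`.
#' @param fit A `growth_fit` (typically the top model of
#'   [fit_growth_models()]).
#' @return Data.frame of class `bci_records`: `chick_id`, `year`, `age1`,
#'   `age2`, `observed_gain_g`, `predicted_gain_g`, `bci`, plus `day` and
#'   `hatch_day` of the second capture when available.
#' @export
compute_bci <- function(masses, fit) {
  stopifnot(inherits(fit, "growth_fit"))
  stopifnot(all(c("chick_id", "year", "age", "mass_g") %in% names(masses)))
  out <- list()
  for (id in unique(masses$chick_id)) {
    m <- masses[masses$chick_id == id, , drop = FALSE]
    m <- m[order(m$age), , drop = FALSE]
    if (nrow(m) < 2) next
    for (j in 2:nrow(m)) {
      a1 <- m$age[j - 1]; a2 <- m$age[j]
      if (a2 <= a1) next
      pred <- predict_mass(fit, a2, year = m$year[j]) -
              predict_mass(fit, a1, year = m$year[j])
      if (!is.finite(pred) || pred <= 0) {
        warning("non-positive predicted gain for chick ", id, "; record skipped")
        next
      }
      out[[length(out) + 1]] <- data.frame(
        chick_id = id, year = m$year[j], age1 = a1, age2 = a2,
        observed_gain_g = m$mass_g[j] - m$mass_g[j - 1],
        predicted_gain_g = pred,
        bci = (m$mass_g[j] - m$mass_g[j - 1]) / pred,
        day = if ("day" %in% names(m)) m$day[j] else NA_real_,
        hatch_day = if ("hatch_day" %in% names(m)) m$hatch_day[j] else NA_real_)
    }
  }
  if (length(out) == 0) {
    stop("no consecutive capture pairs with increasing age")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("bci_records", "data.frame")
  res
}

# internal: small-sample AIC for a gam, penalizing by total effective df
gam_aicc <- function(g) {
  ll <- as.numeric(logLik(g))
  p <- sum(g$edf) + 1  # + residual variance
  n <- length(g$y)
  -2 * ll + 2 * p + 2 * p * (p + 1) / max(n - p - 1, 1)
}

#' Model BCI against resource availability and phenology
#'
#' Two-stage additive modelling of chick body condition. First the
#' influence timescale of the continuous resource covariates is selected:
#' fixed-effects-only additive models are fit with day-of-recapture values
#' and trailing 1-, 3- and 7-day means of daily invertebrate biomass and
#' median body mass, and the timescale with the lowest small-sample AIC
#' wins. Then the full candidate set -- every subset of the fixed effects
#' {biomass, bodymass, hatch date}, each with a penalized cubic regression
#' spline of chick age -- is fit (\pkg{mgcv}, GCV-selected smoothness) and
#' ranked by the same criterion. If no model reaches a weight above 0.90,
#' coefficients are conditionally averaged over models within delta < 4
#' (Akaike weights over that set). Covariate pairs with |Pearson r| >= 0.7
#' are pruned (later-listed covariate dropped) before fitting. Coefficients
#' are reported in original units.
#'
#' @param bci `bci_records` from [compute_bci()]; needs `day` and
#'   `hatch_day` populated.
#' @param series A `daily_resource_series` for the same years.
#' @param windows Candidate trailing windows in days; 0 means day-of.
#' @param k Spline basis dimension for the age smooth (default 8).
#' @param exclude_years Years dropped before fitting (e.g. years without
#'   enough recaptures); default none.
#' @return A list of class `bci_model`: `timescale`, `timescale_table`,
#'   `model_table`, `coefficients` (conditionally averaged estimate, SE,
#'   summed weight per term), `top` (the best \pkg{mgcv} fit), `averaged`.
#' @export
fit_bci_model <- function(bci, series, windows = c(0, 1, 3, 7), k = 8,
                          exclude_years = NULL) {
  stopifnot(inherits(bci, "data.frame"))
  d0 <- bci[!(bci$year %in% exclude_years) & is.finite(bci$day) &
              is.finite(bci$hatch_day), , drop = FALSE]
  if (nrow(d0) < 10) stop("too few BCI records with covariates")

  build <- function(w) {
    d <- d0
    d$biomass <- vapply(seq_len(nrow(d)), function(i)
      rolling_mean(series, d$year[i], d$day[i], max(w, 1), "biomass_mg"),
      numeric(1))
    d$bodymass <- vapply(seq_len(nrow(d)), function(i)
      rolling_mean(series, d$year[i], d$day[i], max(w, 1), "median_bodymass_mg"),
      numeric(1))
    d$hatch <- d$hatch_day
    d$age <- d$age2
    d[complete.cases(d[, c("bci", "biomass", "bodymass", "hatch", "age")]), ]
  }

  # spline basis cannot exceed the number of distinct ages observed
  k <- max(3, min(k, length(unique(d0$age2)) - 1))

  # stage 1: timescale selection on the global fixed-effects structure
  ts_tab <- data.frame(window = windows, AICc = NA_real_)
  for (i in seq_along(windows)) {
    d <- build(windows[i])
    if (nrow(d) < 10) next
    g <- tryCatch(mgcv::gam(bci ~ biomass + bodymass + hatch +
                              s(age, bs = "cr", k = k), data = d),
                  error = function(e) NULL)
    if (!is.null(g)) ts_tab$AICc[i] <- gam_aicc(g)
  }
  if (all(!is.finite(ts_tab$AICc))) stop("no timescale model could be fit")
  best_w <- ts_tab$window[which.min(ts_tab$AICc)]
  d <- build(best_w)

  # collinearity pruning, in listed order
  terms <- c("biomass", "bodymass", "hatch")
  keep <- terms
  for (i in seq_along(terms)) for (j in seq_along(terms)) {
    if (j <= i || !(terms[i] %in% keep) || !(terms[j] %in% keep)) next
    r <- suppressWarnings(stats::cor(d[[terms[i]]], d[[terms[j]]]))
    if (is.finite(r) && abs(r) >= 0.7) {
      warning("dropping '", terms[j], "' (|r| = ", round(abs(r), 2),
              " with '", terms[i], "')")
      keep <- setdiff(keep, terms[j])
    }
  }

  # stage 2: all-subsets candidate set, each with the age smooth
  subsets <- unlist(lapply(0:length(keep), function(m)
    utils::combn(keep, m, simplify = FALSE)), recursive = FALSE)
  models <- list(); rows <- list()
  for (s in subsets) {
    rhs <- paste(c(s, sprintf("s(age, bs = 'cr', k = %d)", k)), collapse = " + ")
    g <- tryCatch(mgcv::gam(as.formula(paste("bci ~", rhs)), data = d),
                  error = function(e) NULL)
    if (is.null(g)) next
    models[[length(models) + 1]] <- g
    rows[[length(rows) + 1]] <- data.frame(
      terms = if (length(s)) paste(s, collapse = "+") else "(age smooth only)",
      AICc = gam_aicc(g))
  }
  tab <- do.call(rbind, rows)
  tab$delta <- tab$AICc - min(tab$AICc)
  tab$weight <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  ord <- order(tab$AICc)
  tab <- tab[ord, ]; models <- models[ord]
  rownames(tab) <- NULL

  averaged <- tab$weight[1] <= 0.90
  avg_set <- if (averaged) which(tab$delta < 4) else 1L
  coefs <- list()
  for (tm in keep) {
    est <- c(); se <- c(); w <- c()
    for (m in avg_set) {
      cf <- coef(models[[m]])
      if (!(tm %in% names(cf))) next
      est <- c(est, cf[tm])
      se <- c(se, sqrt(vcov(models[[m]])[tm, tm]))
      w <- c(w, tab$weight[m])
    }
    if (length(est) == 0) next
    wn <- w / sum(w)
    b <- sum(wn * est)
    # conditional (within-model) averaged SE incl. between-model spread
    s_avg <- sum(wn * sqrt(se^2 + (est - b)^2))
    coefs[[tm]] <- data.frame(term = tm, estimate = b, se = s_avg,
                              weight_sum = sum(w))
  }
  coefs <- if (length(coefs)) do.call(rbind, coefs) else
    data.frame(term = character(), estimate = numeric(), se = numeric(),
               weight_sum = numeric())
  rownames(coefs) <- NULL
  structure(list(timescale = best_w, timescale_table = ts_tab,
                 model_table = tab, coefficients = coefs,
                 top = models[[1]], averaged = averaged, data = d),
            class = "bci_model")
}

#' @export
print.bci_model <- function(x, ...) {
  cat(sprintf("BCI additive model: best timescale = %s-day window%s\n",
              x$timescale,
              if (x$averaged) "; coefficients conditionally averaged (top weight <= 0.90)" else ""))
  print(x$model_table, row.names = FALSE)
  cat("Averaged coefficients (original units):\n")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}
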