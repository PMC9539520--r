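#' Specify the daily-survival model
#'
#' Fixed effects are drawn from `{biomass, bodymass, hatch, age,
#' age_bodymass, age_biomass}` (the interactions are products of the
#' standardized mains); an interaction may only be included together with
#' both of its main effects. Random intercepts may include brood, year and
#' study plot. Coefficients get diffuse Normal(0, `prior_sd`) priors on
#' the standardized scale; random-intercept SDs get Uniform(0, 25)
#' hyperpriors, and the year intercepts carry the model's free mean
#' (hyper-mean prior Normal(0, 1000)) -- hierarchical centring that keeps
#' the intercept identified against the crossed random factors.
#'
#' @param fixed Character vector of fixed effects.
#' @param random Character vector of random-intercept factors.
#' @param prior_sd Prior SD for slope coefficients (standardized scale).
#' @return A list of class `survival_model_spec`.
#' @export
survival_model_spec <- function(fixed = c("biomass", "bodymass", "hatch",
                                          "age", "age_bodymass"),
                                random = c("brood", "year", "plot"),
                                prior_sd = 10) {
  all_fixed <- c("biomass", "bodymass", "hatch", "age", "age_bodymass", "age_biomass")
  stopifnot(all(fixed %in% all_fixed), all(random %in% c("brood", "year", "plot")))
  if ("age_bodymass" %in% fixed && !all(c("age", "bodymass") %in% fixed)) {
    stop("age_bodymass interaction requires both 'age' and 'bodymass' main effects")
  }
  if ("age_biomass" %in% fixed && !all(c("age", "biomass") %in% fixed)) {
    stop("age_biomass interaction requires both 'age' and 'biomass' main effects")
  }
  structure(list(fixed = fixed, random = random, prior_sd = prior_sd),
            class = "survival_model_spec")
}

#' MCMC settings for the survival model
#'
#' Defaults follow the study protocol: three parallel chains of 5000
#' iterations after 600 adaptation and 1000 burn-in iterations, keeping
#' every third sample.
#'
#' @param chains,iterations,adapt,burn_in,thin MCMC controls.
#' @param seed Integer seed for the chains' RNGs.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 3, iterations = 5000, adapt = 600,
                          burn_in = 1000, thin = 3, seed = 1) {
  stopifnot(chains >= 1, iterations > 0, thin >= 1)
  if (floor(iterations / thin) < 1) stop("no retained samples")
  structure(list(chains = chains, iterations = iterations, adapt = adapt,
                 burn_in = burn_in, thin = thin, seed = seed),
            class = "mcmc_settings")
}

# internal: design matrix of standardized fixed effects from histories
survival_design <- function(histories, fixed) {
  cols <- list(biomass = histories$z_biomass,
               bodymass = histories$z_bodymass,
               hatch = histories$z_hatch,
               age = histories$z_age,
               age_bodymass = histories$z_age * histories$z_bodymass,
               age_biomass = histories$z_age * histories$z_biomass)
  X <- do.call(cbind, cols[fixed])
  if (is.null(X)) X <- matrix(0, nrow(histories), 0)
  colnames(X) <- fixed
  X
}

# internal: check pairwise collinearity among included main effects
check_collinearity <- function(X, limit = 0.7) {
  if (ncol(X) < 2) return(invisible(TRUE))
  r <- suppressWarnings(stats::cor(X))
  r[!upper.tri(r)] <- 0
  if (any(abs(r) >= limit, na.rm = TRUE)) {
    bad <- which(abs(r) >= limit, arr.ind = TRUE)[1, ]
    warning(sprintf("covariates '%s' and '%s' are collinear (|r| >= %.1f)",
                    colnames(X)[bad[1]], colnames(X)[bad[2]], limit))
  }
  invisible(TRUE)
}

# internal: assemble the JAGS model string
survival_jags_code <- function(K, random, prior_sd, indicators = FALSE,
                               slab_sd = 2) {
  eta <- c()
  if (K > 0) {
    eta <- c(eta, if (indicators) "inprod(Xb[i,1:K], gb[1:K])" else
               "inprod(X[i,1:K], beta[1:K])")
  }
  has_yr <- "year" %in% random
  if (has_yr) eta <- c(eta, "b.yr[iy[i]]") else eta <- c(eta, "mu")
  if ("brood" %in% random) eta <- c(eta, "b.br[ib[i]]")
  if ("plot" %in% random) eta <- c(eta, "b.pl[ip[i]]")
  sd_slab <- if (indicators) slab_sd else prior_sd
  code <- c("model {",
    "  mu ~ dnorm(0, 0.001)",
    if (K > 0) sprintf("  for (k in 1:K) { beta[k] ~ dnorm(0, %.8f) }", 1 / sd_slab^2),
    if (indicators && K > 0) c(
      "  for (k in 1:K) { g[k] ~ dbern(0.5) }",
      "  for (i in 1:N) { for (k in 1:K) { Xb[i,k] <- X[i,k] } }",
      "  for (k in 1:K) { gb[k] <- g[k] * beta[k] }"),
    if (has_yr) c(
      "  sd.yr ~ dunif(0, 25)",
      "  tau.yr <- pow(sd.yr, -2)",
      "  for (j in 1:NY) { b.yr[j] ~ dnorm(mu, tau.yr) }"),
    if ("brood" %in% random) c(
      "  sd.br ~ dunif(0, 25)",
      "  tau.br <- pow(sd.br, -2)",
      "  for (j in 1:NB) { b.br[j] ~ dnorm(0, tau.br) }"),
    if ("plot" %in% random) c(
      # sum-to-zero constraint: with very few plots a free mean of the
      # plot intercepts is confounded with the model intercept
      "  sd.pl ~ dunif(0, 25)",
      "  tau.pl <- pow(sd.pl, -2)",
      "  for (j in 1:(NP-1)) { b.pl0[j] ~ dnorm(0, tau.pl) }",
      "  for (j in 1:(NP-1)) { b.pl[j] <- b.pl0[j] }",
      "  b.pl[NP] <- -sum(b.pl0[1:(NP-1)])"),
    "  for (i in 1:N) {",
    sprintf("    logit(s[i]) <- %s", paste(eta, collapse = " + ")),
    "    psurv[i] <- pow(s[i], len[i])",
    "    p[i] <- died[i] * (1 - psurv[i]) + (1 - died[i]) * psurv[i]",
    "    ones[i] ~ dbern(p[i])",
    "    loglik[i] <- log(p[i])",
    "  }",
    "}")
  paste(unlist(code), collapse = "\n")
}

# internal: run JAGS and return an mcmc.list plus metadata
run_survival_jags <- function(histories, spec, mcmc, indicators = FALSE,
                              slab_sd = 2, extra_monitors = character(0)) {
  X <- survival_design(histories, spec$fixed)
  mains <- intersect(spec$fixed, c("biomass", "bodymass", "hatch", "age"))
  check_collinearity(survival_design(histories, mains))
  K <- ncol(X)
  dat <- list(N = nrow(histories), len = histories$len,
              died = as.integer(histories$fate == "died_within"),
              ones = rep(1L, nrow(histories)))
  if (K > 0) { dat$X <- X; dat$K <- K }
  if ("year" %in% spec$random) {
    yr <- factor(histories$year)
    dat$iy <- as.integer(yr); dat$NY <- nlevels(yr)
  }
  if ("brood" %in% spec$random) {
    br <- factor(histories$brood_id)
    dat$ib <- as.integer(br); dat$NB <- nlevels(br)
  }
  if ("plot" %in% spec$random) {
    pl <- factor(histories$plot)
    if (nlevels(pl) < 2) {
      spec$random <- setdiff(spec$random, "plot")
    } else {
      dat$ip <- as.integer(pl); dat$NP <- nlevels(pl)
    }
  }
  code <- survival_jags_code(K, spec$random, spec$prior_sd, indicators, slab_sd)
  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (mcmc$seed %% 100000L) * 11L + ch)
  })
  monitors <- c("mu",
                if (K > 0) "beta",
                if (indicators && K > 0) "g",
                if ("year" %in% spec$random) c("sd.yr", "b.yr"),
                if ("brood" %in% spec$random) c("sd.br", "b.br"),
                if ("plot" %in% spec$random) c("sd.pl", "b.pl"),
                "loglik", extra_monitors)
  jm <- rjags::jags.model(textConnection(code), data = dat, inits = inits,
                          n.chains = mcmc$chains, n.adapt = mcmc$adapt,
                          quiet = TRUE)
  if (mcmc$burn_in > 0) update(jm, mcmc$burn_in, progress.bar = "none")
  sam <- rjags::coda.samples(jm, monitors, n.iter = mcmc$iterations,
                             thin = mcmc$thin, progress.bar = "none")
  list(samples = sam, X = X, dat = dat, code = code, spec = spec,
       year_levels = if ("year" %in% spec$random) levels(factor(histories$year)))
}

# internal: split a coda mcmc.list into loglik matrix and parameter list
split_samples <- function(sam) {
  nm <- colnames(sam[[1]])
  ll_cols <- grep("^loglik\\[", nm)
  ll <- do.call(rbind, lapply(sam, function(m) as.matrix(m)[, ll_cols, drop = FALSE]))
  ord <- order(as.integer(sub("^loglik\\[(\\d+)\\]$", "\\1", nm[ll_cols])))
  ll <- ll[, ord, drop = FALSE]
  par <- lapply(sam, function(m) m[, setdiff(seq_along(nm), ll_cols), drop = FALSE])
  class(par) <- "mcmc.list"
  list(loglik = ll, params = par)
}

#' Fit the Bayesian hierarchical known-fate survival model
#'
#' Daily chick survival on the logit scale as a function of standardized
#' resource and phenology covariates, with random intercepts for brood,
#' year and study plot, fit by MCMC (JAGS). The likelihood is the
#' known-fate interval likelihood: survived and censored intervals
#' contribute `s^len`, death intervals `1 - s^len`, with the interval's
#' covariates held at their 3-day trailing means. Convergence requires
#' every Gelman-Rubin Rhat below 1.1; a non-converged fit is flagged but
#' still returned.
#'
#' @param histories An `encounter_histories` object.
#' @param spec A [survival_model_spec()].
#' @param mcmc An [mcmc_settings()].
#' @return A `survival_fit`: `summary` (posterior mean, SD, 95% credible
#'   interval, Rhat, effective size, Bayesian p per parameter), `samples`
#'   (coda), `loglik` (samples x intervals), `waic`, `converged`,
#'   `scaling`, `spec`, `mcmc`, `histories`.
#' @export
fit_survival_mcmc <- function(histories, spec = survival_model_spec(),
                              mcmc = mcmc_settings()) {
  stopifnot(inherits(histories, "data.frame"))
  run <- run_survival_jags(histories, spec, mcmc)
  spec <- run$spec  # single-level factors may have been dropped
  sp <- split_samples(run$samples)
  mat <- do.call(rbind, lapply(sp$params, as.matrix))
  keep <- !grepl("^(b\\.br|b\\.pl)\\[", colnames(mat))
  sum_nm <- colnames(mat)[keep]
  rhat <- tryCatch({
    gd <- coda::gelman.diag(sp$params[, sum_nm, drop = FALSE],
                            multivariate = FALSE, autoburnin = FALSE)
    gd$psrf[, 1]
  }, error = function(e) setNames(rep(NA_real_, length(sum_nm)), sum_nm))
  neff <- tryCatch(coda::effectiveSize(sp$params[, sum_nm, drop = FALSE]),
                   error = function(e) setNames(rep(NA_real_, length(sum_nm)), sum_nm))
  bayes_p <- apply(mat[, sum_nm, drop = FALSE], 2, function(v)
    1 - 2 * min(mean(v > 0), mean(v < 0)))
  summ <- data.frame(
    parameter = sum_nm,
    mean = colMeans(mat[, sum_nm, drop = FALSE]),
    sd = apply(mat[, sum_nm, drop = FALSE], 2, sd),
    ci_2.5 = apply(mat[, sum_nm, drop = FALSE], 2, quantile, 0.025),
    ci_97.5 = apply(mat[, sum_nm, drop = FALSE], 2, quantile, 0.975),
    rhat = rhat[sum_nm], n_eff = neff[sum_nm], bayes_p = bayes_p)
  rownames(summ) <- NULL
  # readable names for the slope coefficients
  bidx <- grep("^beta\\[", summ$parameter)
  if (length(bidx)) {
    ks <- as.integer(sub("^beta\\[(\\d+)\\]$", "\\1", summ$parameter[bidx]))
    summ$parameter[bidx] <- paste0("beta_", spec$fixed[ks])
  }
  slope_rhat <- rhat[grepl("^(beta\\[|mu|sd\\.)", names(rhat))]
  converged <- all(is.finite(slope_rhat)) && all(slope_rhat < 1.1)
  if (!converged) warning("survival MCMC not converged (max Rhat = ",
                          round(max(slope_rhat, na.rm = TRUE), 3), ")")
  structure(list(summary = summ, samples = sp$params, sample_matrix = mat,
                 loglik = sp$loglik, waic = waic(sp$loglik),
                 converged = converged,
                 scaling = attr(histories, "scaling"),
                 spec = spec, mcmc = mcmc, histories = histories,
                 year_levels = run$year_levels, X = run$X),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("Bayesian known-fate survival fit:",
      nrow(x$histories), "intervals,",
      length(unique(x$histories$chick_id)), "chicks;",
      if (x$converged) "converged (all Rhat < 1.1)" else "NOT converged", "\n")
  show <- x$summary[grepl("^(beta_|mu|sd\\.)", x$summary$parameter), ]
  print(cbind(show[1], round(show[-1], 3)), row.names = FALSE)
  cat(sprintf("WAIC = %.1f (SE %.1f)\n", x$waic$waic, x$waic$se))
  invisible(x)
}

#' Watanabe-Akaike information criterion from pointwise log-likelihoods
#'
#' `WAIC = -2 (lppd - p_WAIC)` where `lppd` is the log pointwise posterior
#' predictive density and `p_WAIC` the sum of posterior variances of the
#' pointwise log-likelihood. The SE is computed over the pointwise
#' contributions.
#'
#' @param loglik Matrix of pointwise log-likelihoods, posterior samples in
#'   rows, observations (here: intervals) in columns.
#' @return List: `waic`, `se`, `lppd`, `p_waic`, `elpd` (pointwise vector).
#' @export
waic <- function(loglik) {
  stopifnot(is.matrix(loglik), nrow(loglik) > 1)
  lppd_i <- apply(loglik, 2, function(v) {
    m <- max(v)
    m + log(mean(exp(v - m)))
  })
  p_i <- apply(loglik, 2, var)
  elpd_i <- lppd_i - p_i
  n <- ncol(loglik)
  list(waic = -2 * sum(elpd_i),
       se = 2 * sqrt(n * var(elpd_i)),
       lppd = sum(lppd_i), p_waic = sum(p_i), elpd = elpd_i)
}

#' Compare two survival fits by WAIC
#'
#' @param fit_A,fit_B `survival_fit` objects fit to the same intervals.
#' @return List: `table` (WAIC, SE, p_waic per fit), `winner` (1 or 2,
#'   lower WAIC), `delta`.
#' @export
compare_waic <- function(fit_A, fit_B) {
  stopifnot(inherits(fit_A, "survival_fit"), inherits(fit_B, "survival_fit"))
  if (ncol(fit_A$loglik) != ncol(fit_B$loglik)) {
    stop("fits were not computed on the same data (pointwise dimensions differ)")
  }
  wa <- fit_A$waic; wb <- fit_B$waic
  tab <- data.frame(model = c("A", "B"),
                    waic = c(wa$waic, wb$waic),
                    se = c(wa$se, wb$se),
                    p_waic = c(wa$p_waic, wb$p_waic))
  list(table = tab, winner = which.min(tab$waic), delta = abs(wa$waic - wb$waic))
}

#' Indicator-variable (Kuo-Mallick) model selection
#'
#' Each fixed-effect coefficient is multiplied by a Bernoulli(0.5)
#' indicator sampled alongside the coefficients; the posterior mean of an
#' indicator is the effect's posterior inclusion probability. Effects
#' above `threshold` (default 0.5) enter the selected model, with main
#' effects forced in whenever their interaction is selected. The slab
#' prior SD defaults to 0.75, comparable to plausible effect sizes on the
#' standardized logit scale: a very diffuse slab drives all inclusion
#' probabilities toward zero (the Lindley effect), while a moderate slab
#' leaves a truly uninformative covariate near its 0.5 prior.
#'
#' @param histories An `encounter_histories` object.
#' @param spec Full model [survival_model_spec()].
#' @param mcmc An [mcmc_settings()].
#' @param threshold Inclusion-probability threshold for the final model.
#' @param slab_sd Slab prior SD for coefficients while indicators are on.
#' @return List of class `indicator_selection`: `inclusion` (named
#'   probabilities), `selected` (effect names), `spec_selected`.
#' @export
indicator_selection <- function(histories, spec = survival_model_spec(),
                                mcmc = mcmc_settings(), threshold = 0.5,
                                slab_sd = 0.75) {
  run <- run_survival_jags(histories, spec, mcmc, indicators = TRUE,
                           slab_sd = slab_sd)
  sp <- split_samples(run$samples)
  mat <- do.call(rbind, lapply(sp$params, as.matrix))
  gcols <- grep("^g\\[", colnames(mat))
  ord <- order(as.integer(sub("^g\\[(\\d+)\\]$", "\\1", colnames(mat)[gcols])))
  incl <- colMeans(mat[, gcols[ord], drop = FALSE])
  names(incl) <- spec$fixed
  selected <- names(incl)[incl > threshold]
  for (ia in c("age_bodymass", "age_biomass")) {
    if (ia %in% selected) {
      selected <- union(selected, c("age", sub("age_", "", ia)))
    }
  }
  selected <- intersect(spec$fixed, selected)  # keep declared order
  structure(list(inclusion = incl, selected = selected,
                 spec_selected = survival_model_spec(
                   fixed = selected, random = spec$random,
                   prior_sd = spec$prior_sd),
                 threshold = threshold, slab_sd = slab_sd),
            class = "indicator_selection")
}

#' @export
print.indicator_selection <- function(x, ...) {
  cat("Posterior inclusion probabilities (Kuo-Mallick):\n")
  print(round(x$inclusion, 3))
  cat("Selected (>", x$threshold, "):",
      paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Extrapolate daily survival to fledging by the delta method
#'
#' Fledging probability `F = s^days` with first-order delta-method
#' standard error `SE(F) = days * s^(days-1) * SE(s)`.
#'
#' @param s Daily survival rate, in `(0, 1]`.
#' @param se Standard error of `s`.
#' @param days Days to fledging (default 21).
#' @return List: `fledging`, `se`.
#' @export
#' @examples
#' dsr_to_fledging(0.9, 0.01)  # ~0.109 +/- 0.0255
dsr_to_fledging <- function(s, se = 0, days = 21) {
  if (any(s <= 0) || any(s > 1)) stop("daily survival must lie in (0, 1]")
  stopifnot(all(se >= 0), days > 0)
  list(fledging = s^days, se = days * s^(days - 1) * se)
}

#' Annual daily survival and fledging rates from a survival fit
#'
#' For each posterior draw, the year's daily survival rate is the
#' exposure-weighted mean of the interval survival probabilities of that
#' year's chicks (weights = interval lengths in days). The posterior mean
#' and SD of this DSR are extrapolated to a fledging rate and SE with
#' [dsr_to_fledging()].
#'
#' @param fit A `survival_fit`.
#' @param days Days to fledging (defaults to the histories' fledge age).
#' @return Data.frame: `year`, `dsr`, `dsr_se`, `fledging`, `fledging_se`,
#'   `n_chicks`.
#' @export
annual_fledging_rates <- function(fit, days = NULL) {
  h <- fit$histories
  if (is.null(days)) days <- attr(h, "fledge_age")
  if (is.null(days)) days <- 21
  mat <- fit$sample_matrix
  spec <- fit$spec
  eta <- matrix(0, nrow(mat), nrow(h))
  if (ncol(fit$X) > 0) {
    bcols <- paste0("beta[", seq_len(ncol(fit$X)), "]")
    eta <- eta + mat[, bcols, drop = FALSE] %*% t(fit$X)
  }
  if ("year" %in% spec$random) {
    iy <- match(as.character(h$year), fit$year_levels)
    eta <- eta + mat[, paste0("b.yr[", iy, "]"), drop = FALSE]
  } else {
    eta <- eta + mat[, "mu"]
  }
  if ("brood" %in% spec$random) {
    ib <- as.integer(factor(h$brood_id))
    eta <- eta + mat[, paste0("b.br[", ib, "]"), drop = FALSE]
  }
  if ("plot" %in% spec$random) {
    ip <- as.integer(factor(h$plot))
    eta <- eta + mat[, paste0("b.pl[", ip, "]"), drop = FALSE]
  }
  s <- plogis(eta)
  yrs <- sort(unique(h$year))
  out <- lapply(yrs, function(y) {
    sel <- h$year == y
    w <- h$len[sel] / sum(h$len[sel])
    draws <- as.numeric(s[, sel, drop = FALSE] %*% w)
    f <- dsr_to_fledging(mean(draws), sd(draws), days)
    data.frame(year = y, dsr = mean(draws), dsr_se = sd(draws),
               fledging = f$fledging, fledging_se = f$se,
               n_chicks = length(unique(h$chick_id[sel])))
  })
  do.call(rbind, out)
}
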