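# Per-species exposure-response model.
#
# For each species, the count at site s (grid g, region r) in year t is
# modelled on the log scale as
#
#   log mu = beta0 + beta1 * cumP(g, t) + sum_{j <= t} beta2_j + x_g + y_s + z_r
#
# with Gaussian zero-mean random intercepts x, y, z. The per-year growth
# rates beta2 enter through a binary year matrix whose row for year t has
# ones in all columns from the first non-baseline year through t, and
# cumP(g, t) is the grid's cumulative TEF-adjusted application since the
# baseline year; beta1 is therefore the change in annual log population
# growth per TEF-adjusted kg applied.

#' Reduce a raw visit table to one count per site x year
#'
#' The abundance measure is the maximum count over the (up to two) visits.
#' Years in `excluded_years` are dropped entirely (defaults: 1998, a year
#' without cropping data, and 2001, a year of restricted site access).
#' With `habitat_filter` on, sites that never carried farmland habitat code
#' `"E"` in any survey are dropped, unless listed in `exempt_sites`
#' (emulating survey blocks whose habitat was never recorded but which are
#' known farmland).
#'
#' @param visits Data frame `site_id, grid_id, region_id, year, visit1,
#'   visit2, habitat` (visit2 may be absent or NA).
#' @param habitat_filter Apply the farmland-habitat filter? Default TRUE.
#' @param exempt_sites Sites retained regardless of habitat code.
#' @param excluded_years Years removed from the analysis.
#' @return Data frame `site_id, grid_id, region_id, year, count, habitat_ok`.
#' @export
prepare_counts <- function(visits, habitat_filter = TRUE,
                           exempt_sites = character(),
                           excluded_years = c(1998L, 2001L)) {
  check_columns(visits, c("site_id", "grid_id", "region_id", "year", "visit1"),
                "counts")
  visit_cols <- grep("^visit[0-9]+$", names(visits), value = TRUE)
  vm <- as.matrix(visits[, visit_cols, drop = FALSE])
  if (any(vm < 0, na.rm = TRUE)) {
    stop("visit counts must be non-negative", call. = FALSE)
  }
  count <- suppressWarnings(apply(vm, 1, max, na.rm = TRUE))
  if (any(!is.finite(count))) {
    stop("every site x year needs at least one recorded visit", call. = FALSE)
  }

  ever_farm <- tapply(visits$habitat %||% rep(NA_character_, nrow(visits)),
                      visits$site_id, function(h) any(!is.na(h) & h == "E"))
  habitat_ok <- unname(ever_farm[visits$site_id]) |
    visits$site_id %in% exempt_sites
  out <- data.frame(site_id = visits$site_id, grid_id = visits$grid_id,
                    region_id = visits$region_id, year = visits$year,
                    count = as.integer(count), habitat_ok = habitat_ok,
                    stringsAsFactors = FALSE)
  out <- out[!out$year %in% excluded_years, ]
  if (habitat_filter) out <- out[out$habitat_ok, ]
  if (nrow(out) == 0L) stop("no observations left after filtering", call. = FALSE)
  rownames(out) <- NULL
  out
}

# Cumulative TEF-adjusted exposure for (grid, observation-year) pairs: the
# sum of the grid's exposure over baseline..t-1 (default) or baseline..t.
# Years absent from the exposure table (e.g. an excluded census year)
# contribute 0; recorded exposure in bird-excluded years still accumulates.
cumulative_exposure <- function(grid_id, obs_year, exposure, baseline_year,
                                lag_mode = c("through_t_minus_1", "through_t")) {
  lag_mode <- match.arg(lag_mode)
  if (any(obs_year < baseline_year)) {
    stop("observation year precedes the baseline year", call. = FALSE)
  }
  exp_use <- exposure[exposure$year >= baseline_year, ]
  target_year <- if (lag_mode == "through_t_minus_1") obs_year - 1L else obs_year
  out <- numeric(length(grid_id))
  by_grid <- split(exp_use[, c("year", "tef_adjusted_kg")], exp_use$grid_id)
  for (g in unique(grid_id)) {
    idx <- which(grid_id == g)
    e <- by_grid[[g]]
    if (is.null(e) || nrow(e) == 0L) next   # no recorded exposure: contributes 0
    o <- order(e$year)
    cs <- cumsum(e$tef_adjusted_kg[o])
    pos <- findInterval(target_year[idx], e$year[o])
    out[idx] <- c(0, cs)[pos + 1L]
  }
  out
}

#' Build the model design for one species
#'
#' Assembles the response, the cumulative-exposure covariate, the binary
#' year matrix and the random-effect grouping indices. The year matrix row
#' for an observation in year t has ones exactly in the columns for years
#' baseline+1 through t, so each year column's coefficient is that year's
#' log growth rate. Baseline-year observations have zero cumulative
#' exposure and an all-zero year row. The default lag accumulates exposure
#' through year t-1 (the year whose harvest precedes the breeding-season
#' count); `"through_t"` includes the observation year itself.
#'
#' @param counts Output of [prepare_counts()].
#' @param exposure Grid exposure table (`grid_id, year, tef_adjusted_kg`),
#'   e.g. from [apply_tef()].
#' @param baseline_year First modelled year.
#' @param lag_mode `"through_t_minus_1"` (default) or `"through_t"`.
#' @return A `model_design` list: `response`, `cum_exposure`, `year_matrix`,
#'   `grid_index`, `site_index`, `region_index`, `years`, `baseline_year`,
#'   `data` (a model frame ready for fitting).
#' @export
build_design <- function(counts, exposure, baseline_year,
                         lag_mode = c("through_t_minus_1", "through_t")) {
  lag_mode <- match.arg(lag_mode)
  check_columns(counts, c("site_id", "grid_id", "region_id", "year", "count"),
                "counts")
  check_columns(exposure, c("grid_id", "year", "tef_adjusted_kg"), "exposure")
  if (any(counts$year < baseline_year)) {
    stop("counts contain years before the baseline year", call. = FALSE)
  }
  non_base_grid <- counts$year > baseline_year
  # baseline-year rows need no exposure entry; others must be coverable
  if (any(non_base_grid & !counts$grid_id %in% exposure$grid_id)) {
    stop("some observed grids have no exposure records", call. = FALSE)
  }

  years <- sort(unique(c(baseline_year, counts$year)))
  non_base <- years[years > baseline_year]
  R <- outer(counts$year, non_base, ">=") * 1L
  colnames(R) <- paste0("yr", non_base)

  cum <- cumulative_exposure(counts$grid_id, counts$year, exposure,
                             baseline_year, lag_mode)
  dat <- data.frame(count = counts$count, cum_exposure = cum,
                    grid = factor(counts$grid_id),
                    site = factor(counts$site_id),
                    region = factor(counts$region_id),
                    stringsAsFactors = FALSE)
  dat <- cbind(dat, as.data.frame(R))
  structure(list(response = counts$count, cum_exposure = cum, year_matrix = R,
                 grid_index = dat$grid, site_index = dat$site,
                 region_index = dat$region, years = years,
                 baseline_year = as.integer(baseline_year),
                 lag_mode = lag_mode, obs_year = counts$year, data = dat),
            class = "model_design")
}

#' Fit the per-species log-linear mixed model
#'
#' Maximum-likelihood fit (Laplace approximation, via glmmTMB) of the
#' log-link count model with crossed Gaussian random intercepts for grid
#' square, site and region. Families: `"poisson"`; `"quasi_poisson"`, the
#' classical quasi-likelihood contract — Poisson point estimates with all
#' standard errors inflated by the square root of the Pearson dispersion;
#' and `"negative_binomial"` (quadratic mean-variance), which estimates an
#' extra dispersion parameter. Non-convergence is flagged in the result,
#' never silently ignored.
#'
#' @param design A [build_design()] result.
#' @param family `"poisson"`, `"quasi_poisson"` or `"negative_binomial"`.
#' @param random_effects Set `FALSE` to force all variance components to
#'   zero (a fixed-effects-only log-link regression), used for degenerate-
#'   limit checks.
#' @return A `fit_result` list: `coefficients` (term, estimate, se),
#'   `beta0_hat`, `beta0_se`, `beta1_hat`, `beta1_se`, `beta2` (per-year
#'   data frame), `varcomp` (named variance components), `dispersion`
#'   (Pearson ratio), `overdispersed` flag, `family`, `log_likelihood`,
#'   `converged`, `n_obs`, `fitted` (conditional means), `n_fixed`,
#'   `nb_size` (NB only), `design`, `model` (the underlying fit object).
#' @export
fit_species_model <- function(design,
                              family = c("poisson", "quasi_poisson",
                                         "negative_binomial"),
                              random_effects = TRUE) {
  family <- match.arg(family)
  stopifnot(inherits(design, "model_design"))
  dat <- design$data
  if (length(unique(design$obs_year)) < 2L || nlevels(dat$site) < 2L ||
      all(dat$count == 0L)) {
    stop("degenerate design: need >= 2 years, >= 2 sites and a non-zero response",
         call. = FALSE)
  }
  year_cols <- colnames(design$year_matrix)
  # drop year columns with no variation (e.g. a final year nobody observed)
  keep <- year_cols[vapply(year_cols, function(cl) stats::var(dat[[cl]]) > 0,
                           logical(1))]
  re_terms <- if (random_effects) c("(1 | grid)", "(1 | site)", "(1 | region)")
              else character()
  fml <- stats::reformulate(c("cum_exposure", keep, re_terms),
                            response = "count")
  tmb_family <- if (family == "negative_binomial") glmmTMB::nbinom2()
                else stats::poisson()
  fit <- suppressWarnings(glmmTMB::glmmTMB(fml, data = dat, family = tmb_family))

  co <- summary(fit)$coefficients$cond
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  converged <- isTRUE(fit$fit$convergence == 0) &&
    isTRUE(fit$sdr$pdHess %||% TRUE) && all(is.finite(se)) && all(se > 0)
  mu <- stats::fitted(fit)
  nb_size <- if (family == "negative_binomial") stats::sigma(fit) else NA_real_
  n_fixed <- length(est)
  n_var <- if (random_effects) 3L else 0L
  rdf <- nrow(dat) - n_fixed - n_var - (family == "negative_binomial")
  dispersion <- pearson_dispersion(dat$count, mu, rdf,
                                   nb_size = if (is.na(nb_size)) NULL else nb_size)
  if (family == "quasi_poisson") se <- se * sqrt(dispersion)

  vc <- if (random_effects) {
    v <- glmmTMB::VarCorr(fit)$cond
    c(sigma2_grid = as.numeric(v$grid), sigma2_site = as.numeric(v$site),
      sigma2_region = as.numeric(v$region))
  } else c(sigma2_grid = 0, sigma2_site = 0, sigma2_region = 0)

  terms <- rownames(co)
  beta2 <- data.frame(year = as.integer(sub("^yr", "", keep)),
                      estimate = unname(est[keep]), se = unname(se[keep]))
  structure(list(
    coefficients = data.frame(term = terms, estimate = unname(est),
                              se = unname(se), stringsAsFactors = FALSE),
    beta0_hat = unname(est[["(Intercept)"]]), beta0_se = unname(se[["(Intercept)"]]),
    beta1_hat = unname(est[["cum_exposure"]]), beta1_se = unname(se[["cum_exposure"]]),
    beta2 = beta2, varcomp = vc, dispersion = dispersion,
    overdispersed = dispersion > 1.5, family = family,
    log_likelihood = as.numeric(stats::logLik(fit)), converged = converged,
    n_obs = nrow(dat), fitted = as.numeric(mu), n_fixed = n_fixed,
    residual_df = rdf, nb_size = nb_size, design = design, model = fit),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Log-linear mixed count model (%s), %d observations\n",
              x$family, x$n_obs))
  cat(sprintf("  exposure effect beta1 = %.5g (SE %.3g); %.2f%% change per TEF-adjusted kg\n",
              x$beta1_hat, x$beta1_se, 100 * (exp(x$beta1_hat) - 1)))
  cat(sprintf("  dispersion %.2f%s; converged: %s\n", x$dispersion,
              if (x$overdispersed) " (overdispersed)" else "", x$converged))
  invisible(x)
}

#' Pearson dispersion from observed counts and fitted means
#'
#' Building block for [overdispersion_ratio()]: the sum of squared Pearson
#' residuals divided by the residual degrees of freedom. With the Poisson
#' variance, a saturated fit (fitted means equal to the observed counts)
#' gives exactly 0.
#'
#' @param observed Observed counts.
#' @param fitted Fitted means (> 0).
#' @param residual_df Residual degrees of freedom (> 0).
#' @param nb_size Negative-binomial size parameter; `NULL` (default) uses
#'   the Poisson variance.
#' @return Dispersion ratio (scalar).
#' @export
pearson_dispersion <- function(observed, fitted, residual_df, nb_size = NULL) {
  if (residual_df <= 0) stop("residual degrees of freedom must be > 0", call. = FALSE)
  if (any(fitted <= 0)) stop("fitted means must be positive", call. = FALSE)
  v <- if (is.null(nb_size)) fitted else fitted + fitted^2 / nb_size
  sum((observed - fitted)^2 / v) / residual_df
}

#' Pearson overdispersion ratio
#'
#' Sum of squared Pearson residuals over the residual degrees of freedom
#' (observations minus fixed-effect and variance parameters). Ratios above
#' 1.5 flag the fit as overdispersed, the trigger for refitting with the
#' quasi-Poisson (or negative-binomial) family.
#'
#' @param fit A [fit_species_model()] result.
#' @return List `ratio`, `flag` (ratio > 1.5), `residual_df`.
#' @export
overdispersion_ratio <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged) stop("overdispersion ratio requires a converged fit", call. = FALSE)
  if (fit$residual_df <= 0) stop("residual degrees of freedom <= 0", call. = FALSE)
  list(ratio = fit$dispersion, flag = fit$dispersion > 1.5,
       residual_df = fit$residual_df)
}

#' Simulation-based zero-inflation check
#'
#' Simulates `n_sim` response vectors from the fitted model (conditional on
#' the estimated random effects) and compares the observed number of zero
#' counts with the simulated distribution; the p-value is the two-sided
#' tail probability of a zero count at least as extreme as observed.
#'
#' @param fit A converged [fit_species_model()] result.
#' @param n_sim Number of simulated response vectors (error if < 1; warning
#'   if < 100, where the tail estimate is unstable).
#' @param rng_seed Integer seed.
#' @return List `observed_zeros`, `expected_zeros` (simulated mean),
#'   `sim_quantiles` (2.5/50/97.5%), `p`.
#' @export
zero_inflation_check <- function(fit, n_sim = 1000L, rng_seed = 1L) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged) stop("zero-inflation check requires a converged fit", call. = FALSE)
  if (n_sim < 1L) stop("n_sim must be >= 1", call. = FALSE)
  if (n_sim < 100L) warning("n_sim < 100 gives an unstable tail estimate", call. = FALSE)
  set.seed(derive_seed(rng_seed, "zeroinfl"))
  mu <- fit$fitted
  sim_zeros <- vapply(seq_len(n_sim), function(i) {
    y <- if (fit$family == "negative_binomial") {
      stats::rnbinom(length(mu), mu = mu, size = fit$nb_size)
    } else stats::rpois(length(mu), mu)
    sum(y == 0L)
  }, numeric(1))
  obs <- sum(fit$design$response == 0L)
  p_hi <- (sum(sim_zeros >= obs) + 1) / (n_sim + 1)
  p_lo <- (sum(sim_zeros <= obs) + 1) / (n_sim + 1)
  list(observed_zeros = obs, expected_zeros = mean(sim_zeros),
       sim_quantiles = stats::quantile(sim_zeros, c(0.025, 0.5, 0.975)),
       p = min(1, 2 * min(p_hi, p_lo)))
}

#' Wald z-test for a fitted coefficient
#'
#' @param fit A converged [fit_species_model()] result.
#' @param coefficient Term label (e.g. `"cum_exposure"`, `"(Intercept)"`,
#'   `"yr1996"`).
#' @return List `estimate`, `se`, `z`, `p` (two-sided, standard normal).
#' @export
wald_test <- function(fit, coefficient = "cum_exposure") {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged) stop("Wald test requires a converged fit", call. = FALSE)
  i <- match(coefficient, fit$coefficients$term)
  if (is.na(i)) {
    stop(sprintf("unknown coefficient '%s'", coefficient), call. = FALSE)
  }
  est <- fit$coefficients$estimate[i]
  se <- fit$coefficients$se[i]
  if (se <= 0) stop("standard error must be positive", call. = FALSE)
  z <- est / se
  list(estimate = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}
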