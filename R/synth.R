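# Synthetic landscapes, usage surveys, diet tables and bird counts.
#
# The generator reproduces the statistical structure the downstream stages
# assume — biennial regional usage surveys with a compound changeover,
# grid-level crop areas with missing census years whose regional totals are
# still surveyed, and two-visit site counts from the log-linear mixed model
# — so the whole pipeline is testable without the licensed survey data.

#' Configuration for a synthetic agricultural landscape
#'
#' Defaults mirror the packaged study design: a 1994-2014 window, biennial
#' usage surveys, the dominant seed-treatment compound switching from
#' imidacloprid to clothianidin in 2008, and 1998 missing from the
#' grid-level census.
#'
#' @param n_regions Number of regions.
#' @param grids_per_region 5x5 km grid squares per region.
#' @param years Strictly increasing calendar years covered.
#' @param crops Crop labels.
#' @param compounds Compound labels; the first dominates usage before
#'   `changeover_year`, the second after.
#' @param changeover_year Year the dominant compound switches (within `years`).
#' @param survey_cadence Years between usage surveys (>= 1; surveys fall on
#'   `years[1]`, `years[1] + cadence`, ...).
#' @param missing_census_years Years with no grid-level crop areas (regional
#'   survey totals remain available).
#' @param mean_area_ha Mean cropped area per grid x crop (gamma distributed;
#'   the heavy right tail mimics the concentration of arable land).
#' @param rng_seed Integer seed for the landscape stream.
#' @return A `landscape_config` list, validated.
#' @export
landscape_config <- function(n_regions = 4, grids_per_region = 10,
                             years = 1994:2014,
                             crops = c("wheat", "barley", "oilseed_rape", "sugar_beet"),
                             compounds = c("IMI", "CTD", "THX"),
                             changeover_year = 2008, survey_cadence = 2,
                             missing_census_years = c(1998, 1999, 2001, 2002,
                                                      2006:2009, 2011:2014),
                             mean_area_ha = 100, rng_seed = 1L) {
  if (length(years) == 0L || length(crops) == 0L) {
    stop("years and crops must be non-empty", call. = FALSE)
  }
  if (any(diff(years) <= 0)) stop("years must be strictly increasing", call. = FALSE)
  if (!changeover_year %in% years) {
    stop("changeover_year must lie within years", call. = FALSE)
  }
  if (survey_cadence < 1) stop("survey_cadence must be >= 1", call. = FALSE)
  if (length(compounds) < 2L) stop("need at least two compounds", call. = FALSE)
  structure(list(n_regions = n_regions, grids_per_region = grids_per_region,
                 years = as.integer(years), crops = crops, compounds = compounds,
                 changeover_year = as.integer(changeover_year),
                 survey_cadence = as.integer(survey_cadence),
                 missing_census_years = as.integer(missing_census_years),
                 mean_area_ha = mean_area_ha, rng_seed = as.integer(rng_seed)),
            class = "landscape_config")
}

#' Generative parameters for synthetic bird counts
#'
#' Parameters of the log-linear count model the pipeline estimates:
#' `log(mean) = beta0 + beta1 * cumP + sum(beta2 up to year t) + grid + site
#' + region intercepts`, with Gaussian zero-mean random intercepts.
#'
#' @param beta0 Log baseline abundance in the baseline year.
#' @param beta1 Change in log population growth per TEF-adjusted kg.
#' @param beta2 Vector of per-year background log growth rates, one per
#'   non-baseline year (recycled if length 1).
#' @param sigma_grid,sigma_site,sigma_region Random-intercept SDs (>= 0).
#' @param family `"poisson"` or `"negative_binomial"`.
#' @param nb_dispersion Negative-binomial size parameter (> 0); smaller
#'   means more overdispersion. Ignored for Poisson.
#' @param rng_seed Integer seed for the count stream.
#' @return A `generative_params` list, validated.
#' @export
generative_params <- function(beta0 = 1.5, beta1 = -0.005, beta2 = 0.01,
                              sigma_grid = 0.3, sigma_site = 0.4,
                              sigma_region = 0.2,
                              family = c("poisson", "negative_binomial"),
                              nb_dispersion = 1, rng_seed = 1L) {
  family <- match.arg(family)
  if (any(c(sigma_grid, sigma_site, sigma_region) < 0)) {
    stop("random-intercept SDs must be >= 0", call. = FALSE)
  }
  if (family == "negative_binomial" && nb_dispersion <= 0) {
    stop("nb_dispersion must be > 0 for the negative binomial", call. = FALSE)
  }
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2,
                 sigma_grid = sigma_grid, sigma_site = sigma_site,
                 sigma_region = sigma_region, family = family,
                 nb_dispersion = nb_dispersion, rng_seed = as.integer(rng_seed)),
            class = "generative_params")
}

#' Simulate a landscape: crop areas, usage surveys and regional totals
#'
#' Grid x crop x year areas are gamma draws (shape 2), so areas are
#' non-negative and right-skewed. Regional June-survey totals are the exact
#' regional sums for every year — including years later removed from the
#' grid-level census — which makes the JSA-based interpolation rules
#' exactly checkable. Usage mass per region x crop x compound x survey year
#' is cropped area times a per-compound application rate whose compound
#' shares flip at the changeover year (first compound dominant before,
#' second after).
#'
#' @param config A [landscape_config()].
#' @return List with `crop_areas` (grid census, missing years removed),
#'   `usage` (survey years only), `jsa` (regional totals, all years) and
#'   `layout` (grid -> region lookup).
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(derive_seed(config$rng_seed, "landscape"))
  n_grids <- config$n_regions * config$grids_per_region
  grid_id <- sprintf("G%03d", seq_len(n_grids))
  region_id <- sprintf("R%d", rep(seq_len(config$n_regions),
                                  each = config$grids_per_region))
  layout <- data.frame(grid_id = grid_id, region_id = region_id,
                       stringsAsFactors = FALSE)

  full <- expand.grid(grid_id = grid_id, year = config$years,
                      crop = config$crops, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  full$region_id <- layout$region_id[match(full$grid_id, layout$grid_id)]
  # persistent grid x crop propensity times yearly noise: grids keep their
  # cropping character across years, as real squares do
  base <- stats::rgamma(n_grids * length(config$crops), shape = 2,
                        scale = config$mean_area_ha / 2)
  names(base) <- paste(rep(grid_id, times = length(config$crops)),
                       rep(config$crops, each = n_grids))
  full$area_ha <- base[paste(full$grid_id, full$crop)] *
    stats::rgamma(nrow(full), shape = 25, rate = 25)

  jsa <- stats::aggregate(area_ha ~ region_id + year + crop, data = full, FUN = sum)
  national <- stats::aggregate(area_ha ~ year + crop, data = full, FUN = sum)
  national$region_id <- "NATIONAL"
  jsa <- rbind(jsa[, c("region_id", "year", "crop", "area_ha")],
               national[, c("region_id", "year", "crop", "area_ha")])

  survey_years <- config$years[seq(1L, length(config$years),
                                   by = config$survey_cadence)]
  usage <- merge(jsa[jsa$region_id != "NATIONAL" & jsa$year %in% survey_years, ],
                 data.frame(compound = config$compounds, stringsAsFactors = FALSE))
  usage$share <- compound_shares(usage$compound, usage$year, config)
  # application rate ~ 0.02 kg active substance per treated hectare, with
  # survey-to-survey noise
  rate <- 0.02 * stats::rgamma(nrow(usage), shape = 50, rate = 50)
  usage$mass_kg <- usage$area_ha * rate * usage$share
  usage <- data.frame(region_id = usage$region_id, survey_year = usage$year,
                      crop = usage$crop, compound = usage$compound,
                      mass_kg = usage$mass_kg, stringsAsFactors = FALSE)
  usage <- usage[order(usage$region_id, usage$survey_year, usage$crop,
                       usage$compound), ]

  crop_areas <- full[!full$year %in% config$missing_census_years,
                     c("grid_id", "region_id", "year", "crop", "area_ha")]
  rownames(crop_areas) <- rownames(usage) <- rownames(jsa) <- NULL
  list(crop_areas = crop_areas, usage = usage, jsa = jsa, layout = layout)
}

# Compound mix of total usage mass: the first compound takes the dominant
# share before the changeover year, the second after; any further compounds
# split the remainder evenly.
compound_shares <- function(compound, year, config) {
  k <- length(config$compounds)
  rest <- if (k > 2L) 0.1 / (k - 2L) else 0
  pre <- stats::setNames(c(0.75, 0.15, rep(rest, k - 2L))[seq_len(k)],
                         config$compounds)
  post <- stats::setNames(c(0.15, 0.75, rep(rest, k - 2L))[seq_len(k)],
                          config$compounds)
  if (k == 2L) { pre <- pre / sum(pre); post <- post / sum(post) }
  ifelse(year < config$changeover_year,
         lookup(compound, pre, "compound"),
         lookup(compound, post, "compound"))
}

#' Simulate two-visit bird counts over a grid exposure surface
#'
#' For each site x year, the expected count is
#' `exp(beta0 + beta1 * cumP + sum(beta2) + grid + site + region effect)`,
#' where `cumP` is the cumulative TEF-adjusted exposure of the site's grid
#' (same rule as [build_design()]), and each visit's count is an independent
#' draw from the configured family with that mean. All sites carry farmland
#' habitat code `"E"` unless a fraction is configured otherwise, to
#' exercise the habitat filter.
#'
#' @param exposure Grid exposure table (`grid_id, year, tef_adjusted_kg`).
#' @param site_layout Data frame `site_id, grid_id, region_id`.
#' @param params A [generative_params()].
#' @param baseline_year First modelled year; must be in the exposure years.
#' @param n_visits Visits per site x year (default 2).
#' @param years Years to generate counts for (default: all exposure years).
#' @param frac_nonfarm Fraction of sites given habitat code `"G"`.
#' @param frac_missing_habitat Fraction of sites with habitat `NA`
#'   (emulating survey blocks where habitat was never recorded).
#' @param lag_mode Cumulative-exposure lag, as in [build_design()].
#' @return Data frame `site_id, grid_id, region_id, year, visit1, visit2,
#'   habitat` (visit columns up to `n_visits`).
#' @export
simulate_counts <- function(exposure, site_layout, params, baseline_year,
                            n_visits = 2L, years = NULL, frac_nonfarm = 0,
                            frac_missing_habitat = 0,
                            lag_mode = c("through_t_minus_1", "through_t")) {
  stopifnot(inherits(params, "generative_params"))
  lag_mode <- match.arg(lag_mode)
  check_columns(exposure, c("grid_id", "year", "tef_adjusted_kg"), "exposure")
  check_columns(site_layout, c("site_id", "grid_id", "region_id"), "site_layout")
  years <- sort(unique(as.integer(years %||% unique(exposure$year))))
  if (!baseline_year %in% years) {
    stop("baseline_year must be among the generated years", call. = FALSE)
  }
  missing_grid <- setdiff(site_layout$grid_id, exposure$grid_id)
  if (length(missing_grid) > 0L) {
    stop(sprintf("no exposure for grid(s): %s",
                 paste(missing_grid, collapse = ", ")), call. = FALSE)
  }
  set.seed(derive_seed(params$rng_seed, "counts"))

  years <- years[years >= baseline_year]
  obs <- expand.grid(site_id = site_layout$site_id, year = years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  obs$grid_id <- site_layout$grid_id[match(obs$site_id, site_layout$site_id)]
  obs$region_id <- site_layout$region_id[match(obs$site_id, site_layout$site_id)]
  obs$cum_exposure <- cumulative_exposure(obs$grid_id, obs$year, exposure,
                                          baseline_year, lag_mode)

  non_base <- years[years > baseline_year]
  beta2 <- rep(params$beta2, length.out = length(non_base))
  cum_beta2 <- c(0, cumsum(beta2))          # indexed by match(year, years)
  grids <- unique(site_layout$grid_id)
  regions <- unique(site_layout$region_id)
  x_g <- stats::setNames(stats::rnorm(length(grids), 0, params$sigma_grid), grids)
  y_s <- stats::setNames(stats::rnorm(nrow(site_layout), 0, params$sigma_site),
                         site_layout$site_id)
  z_r <- stats::setNames(stats::rnorm(length(regions), 0, params$sigma_region),
                         regions)
  eta <- params$beta0 + params$beta1 * obs$cum_exposure +
    cum_beta2[match(obs$year, years)] +
    x_g[obs$grid_id] + y_s[obs$site_id] + z_r[obs$region_id]
  mu <- exp(eta)

  draw <- function() {
    if (params$family == "poisson") stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = params$nb_dispersion)
  }
  for (v in seq_len(n_visits)) obs[[paste0("visit", v)]] <- draw()

  habitat <- rep("E", nrow(site_layout))
  n_sites <- nrow(site_layout)
  if (frac_nonfarm > 0) {
    habitat[sample.int(n_sites, round(frac_nonfarm * n_sites))] <- "G"
  }
  if (frac_missing_habitat > 0) {
    pool <- which(habitat == "E")
    habitat[sample(pool, min(length(pool),
                             round(frac_missing_habitat * n_sites)))] <- NA
  }
  obs$habitat <- stats::setNames(habitat, site_layout$site_id)[obs$site_id]
  obs$cum_exposure <- NULL
  obs <- obs[order(obs$site_id, obs$year),
             c("site_id", "grid_id", "region_id", "year",
               paste0("visit", seq_len(n_visits)), "habitat")]
  rownames(obs) <- NULL
  obs
}

#' Simulate species diet profiles with known exposure groups
#'
#' Draws each species' true group from `group_weights`, then generates
#' life-stage proportions consistent with that group under the
#' classification rules of [assign_exposure_group()]: high has one stage at
#' 50% or above, medium has all stages below 50 with at least one at 1% or
#' more, low has all zeros. Round-trip classification recovers the true
#' group by construction.
#'
#' @param n_species Number of species (> 0).
#' @param group_weights Probabilities for (high, medium, low); must sum to 1.
#' @param rng_seed Integer seed.
#' @return Data frame `species, prop_breeding, prop_nonbreeding, prop_chick,
#'   override_group, true_group`.
#' @export
simulate_diet_profiles <- function(n_species,
                                   group_weights = c(high = 8, medium = 9, low = 5) / 22,
                                   rng_seed = 1L) {
  if (n_species < 1L) stop("n_species must be >= 1", call. = FALSE)
  if (abs(sum(group_weights) - 1) > 1e-8) {
    stop("group_weights must sum to 1", call. = FALSE)
  }
  set.seed(derive_seed(rng_seed, "diet"))
  groups <- sample(c("high", "medium", "low"), n_species, replace = TRUE,
                   prob = group_weights)
  props <- t(vapply(groups, function(g) {
    switch(g,
           low = c(0, 0, 0),
           medium = {
             p <- stats::runif(3, 0, 49)
             p[sample.int(3, 1)] <- stats::runif(1, 1, 49)
             p
           },
           high = {
             p <- stats::runif(3, 0, 49)
             p[sample.int(3, 1)] <- stats::runif(1, 50, 100)
             p
           })
  }, numeric(3)))
  data.frame(species = sprintf("sp%03d", seq_len(n_species)),
             prop_breeding = props[, 1], prop_nonbreeding = props[, 2],
             prop_chick = props[, 3], override_group = NA_character_,
             true_group = groups, stringsAsFactors = FALSE, row.names = NULL)
}
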