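test_that("visit tables reduce to max counts with year and habitat filters", {
  vis <- data.frame(site_id = c("S1", "S1", "S2", "S3"),
                    grid_id = "G001", region_id = "R1",
                    year = c(2000L, 2001L, 2000L, 2000L),
                    visit1 = c(3L, 5L, 0L, 2L), visit2 = c(7L, 1L, 4L, NA),
                    habitat = c("E", "E", "G", NA),
                    stringsAsFactors = FALSE)
  got <- prepare_counts(vis, habitat_filter = FALSE)
  expect_equal(got$count[got$site_id == "S1"], 7L)   # max over visits
  expect_equal(got$count[got$site_id == "S3"], 2L)   # NA visit ignored
  expect_false(2001 %in% got$year)                   # excluded year dropped

  # habitat truth table: non-farmland and unrecorded sites drop unless exempt
  filt <- prepare_counts(vis, habitat_filter = TRUE)
  expect_equal(unique(filt$site_id), "S1")
  exempt <- prepare_counts(vis, habitat_filter = TRUE,
                           exempt_sites = c("S2", "S3"))
  expect_setequal(unique(exempt$site_id), c("S1", "S2", "S3"))
  # a site farmland in any one survey is kept in all its years
  vis2 <- vis
  vis2$habitat <- c("G", "E", "G", "E")
  expect_setequal(unique(prepare_counts(vis2)$site_id), c("S1", "S3"))

  vis$visit1[1] <- -1L
  expect_error(prepare_counts(vis), "non-negative")
})

test_that("the design carries cumulative exposure and the binary year matrix", {
  expo <- data.frame(grid_id = "G001", year = 1994:1997,
                     tef_adjusted_kg = c(2, 3, 0, 1))
  counts <- data.frame(site_id = "S1", grid_id = "G001", region_id = "R1",
                       year = 1994:1997, count = c(4L, 5L, 3L, 6L))
  des <- build_design(counts, expo, baseline_year = 1994)

  # baseline observation: zero exposure, all-zero year row
  expect_equal(des$cum_exposure[des$obs_year == 1994], 0)
  expect_equal(sum(des$year_matrix[des$obs_year == 1994, ]), 0)
  # default lag sums exposure through t - 1
  expect_equal(des$cum_exposure[des$obs_year == 1997], 2 + 3 + 0)
  des_t <- build_design(counts, expo, 1994, lag_mode = "through_t")
  expect_equal(des_t$cum_exposure[des_t$obs_year == 1997], 2 + 3 + 0 + 1)
  # 1996 row has ones exactly in the 1995 and 1996 columns
  r96 <- des$year_matrix[des$obs_year == 1996, ]
  expect_equal(r96, c(yr1995 = 1, yr1996 = 1, yr1997 = 0))

  # an exposure year absent from the table contributes zero
  gap <- expo[expo$year != 1995, ]
  des_gap <- build_design(counts, gap, 1994)
  expect_equal(des_gap$cum_exposure[des_gap$obs_year == 1997], 2 + 0)

  expect_error(build_design(transform(counts, year = year - 10), expo, 1994),
               "before the baseline")
})

test_that("design invariants hold on generated instances", {
  for (seed in 1:5) {
    expo <- make_exposure(5, 2000:2006, seed = seed)
    layout <- make_layout(5)
    des <- make_design(expo, layout,
                       generative_params(rng_seed = seed), 2000)
    expect_true(all(des$year_matrix %in% c(0L, 1L)))
    # each row is a prefix of ones up to the observation year
    for (i in sample(nrow(des$data), 20)) {
      expected <- as.numeric(des$years[-1] <= des$obs_year[i])
      expect_equal(unname(des$year_matrix[i, ]), expected)
    }
    expect_true(all(des$cum_exposure[des$obs_year == 2000] == 0))
    # cumulative exposure non-decreasing in t within a grid
    by_grid <- split(seq_len(nrow(des$data)), des$grid_index)
    for (idx in by_grid) {
      o <- idx[order(des$obs_year[idx])]
      expect_true(all(diff(des$cum_exposure[o][!duplicated(des$obs_year[o])]) >= -1e-12))
    }
  }
})

test_that("with variance components forced off the fit matches a plain GLM", {
  expo <- make_exposure(8, 2000:2005, seed = 7)
  layout <- make_layout(8, sites_per_grid = 3)
  p <- generative_params(beta0 = 1.4, beta1 = -0.02, beta2 = 0.03,
                         sigma_grid = 0, sigma_site = 0, sigma_region = 0,
                         rng_seed = 77L)
  des <- make_design(expo, layout, p, 2000)
  fit <- fit_species_model(des, family = "poisson", random_effects = FALSE)
  ref <- stats::glm(
    count ~ cum_exposure + yr2001 + yr2002 + yr2003 + yr2004 + yr2005,
    data = des$data, family = stats::poisson())
  expect_equal(fit$coefficients$estimate,
               unname(stats::coef(ref)[fit$coefficients$term]),
               tolerance = 1e-4)
  expect_equal(fit$varcomp, c(sigma2_grid = 0, sigma2_site = 0,
                              sigma2_region = 0))
})

test_that("fixed effects agree with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  expo <- make_exposure(6, 2000:2004, seed = 9)
  layout <- make_layout(6, sites_per_grid = 2, n_regions = 2)
  p <- generative_params(beta0 = 1.6, beta1 = -0.03, beta2 = 0.05,
                         sigma_grid = 0.3, sigma_site = 0.3, sigma_region = 0.1,
                         rng_seed = 99L)
  des <- make_design(expo, layout, p, 2000)
  fit <- fit_species_model(des, family = "poisson")
  ref <- lme4::glmer(
    count ~ cum_exposure + yr2001 + yr2002 + yr2003 + yr2004 +
      (1 | grid) + (1 | site) + (1 | region),
    data = des$data, family = stats::poisson())
  ours <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  theirs <- lme4::fixef(ref)
  expect_equal(ours[names(theirs)], theirs, tolerance = 1e-3)
})

test_that("quasi-Poisson inflates every standard error by sqrt(dispersion)", {
  expo <- make_exposure(6, 2000:2004, seed = 13)
  layout <- make_layout(6, sites_per_grid = 3)
  p <- generative_params(beta0 = 1.2, beta1 = 0, family = "negative_binomial",
                         nb_dispersion = 1.5, rng_seed = 131L)
  des <- make_design(expo, layout, p, 2000)
  pois <- fit_species_model(des, family = "poisson")
  quasi <- fit_species_model(des, family = "quasi_poisson")
  expect_equal(quasi$coefficients$estimate, pois$coefficients$estimate)
  expect_equal(quasi$coefficients$se,
               pois$coefficients$se * sqrt(pois$dispersion))
  expect_equal(quasi$dispersion, pois$dispersion)
})

test_that("the Pearson ratio is calibrated and flags real overdispersion", {
  # saturated toy: fitted means equal observed counts exactly
  expect_equal(pearson_dispersion(c(1, 4, 2), c(1, 4, 2), residual_df = 2), 0)
  expect_error(pearson_dispersion(1, 1, 0), "> 0")

  # Poisson data at known means concentrates near 1
  set.seed(17)
  mu <- rgamma(3000, 3, 0.5)
  y <- rpois(3000, mu)
  expect_gt(pearson_dispersion(y, mu, 2999), 0.8)
  expect_lt(pearson_dispersion(y, mu, 2999), 1.2)

  # strongly overdispersed counts fit with Poisson raise the flag
  expo <- make_exposure(8, 2000:2005, seed = 19)
  layout <- make_layout(8, sites_per_grid = 4)
  pnb <- generative_params(beta0 = 1.8, beta1 = 0,
                           family = "negative_binomial", nb_dispersion = 0.4,
                           rng_seed = 191L)
  des <- make_design(expo, layout, pnb, 2000)
  fit <- fit_species_model(des, family = "poisson")
  od <- overdispersion_ratio(fit)
  expect_true(od$flag)
  expect_gt(od$ratio, 1.5)
})

test_that("the zero-inflation check is calibrated and detects injected zeros", {
  expo <- make_exposure(6, 2000:2004, seed = 23)
  layout <- make_layout(6, sites_per_grid = 6)
  p <- generative_params(beta0 = 0.2, beta1 = 0, sigma_grid = 0.2,
                         sigma_site = 0.3, sigma_region = 0.1, rng_seed = 231L)
  des <- make_design(expo, layout, p, 2000)
  fit <- fit_species_model(des, family = "poisson")

  expect_error(zero_inflation_check(fit, n_sim = 0), ">= 1")
  expect_warning(zero_inflation_check(fit, n_sim = 50), "unstable")

  # data regenerated from the fitted model give uniform p-values
  set.seed(77)
  ps <- replicate(200, {
    fake <- fit
    fake$design$response <- rpois(length(fit$fitted), fit$fitted)
    zero_inflation_check(fake, n_sim = 600,
                         rng_seed = sample.int(1e6, 1))$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)

  # halving the data to zeros is decisively detected
  inflated <- fit
  y <- rpois(length(fit$fitted), pmax(fit$fitted, 5))
  y[seq(1, length(y), by = 2)] <- 0L
  inflated$design$response <- y
  expect_lt(zero_inflation_check(inflated, n_sim = 600, rng_seed = 5)$p, 0.01)
})

test_that("Wald tests follow the normal reference", {
  expo <- make_exposure(4, 2000:2002, seed = 29)
  layout <- make_layout(4)
  des <- make_design(expo, layout, generative_params(rng_seed = 291L), 2000)
  fit <- fit_species_model(des, family = "poisson")
  wt <- wald_test(fit, "cum_exposure")
  expect_equal(wt$z, fit$beta1_hat / fit$beta1_se)
  expect_equal(wt$p, 2 * pnorm(-abs(wt$z)))
  expect_error(wald_test(fit, "not_a_term"), "unknown coefficient")

  # z = 0 gives p = 1; z = 1.96 gives p ~ 0.05 (identity on a doctored fit)
  fake <- fit
  fake$coefficients$estimate[fake$coefficients$term == "cum_exposure"] <- 0
  expect_equal(wald_test(fake, "cum_exposure")$p, 1)
  fake$coefficients$estimate[fake$coefficients$term == "cum_exposure"] <-
    1.96 * fake$coefficients$se[fake$coefficients$term == "cum_exposure"]
  expect_equal(wald_test(fake, "cum_exposure")$p, 0.05, tolerance = 1e-3)
})
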