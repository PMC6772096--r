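test_that("TEFs are exact toxicity ratios with the reference at 1", {
  expect_equal(compute_tef(152, 2000), 0.076)
  expect_equal(format_tef(compute_tef(152, 2000)), 0.08)
  expect_equal(format_tef(compute_tef(152, 2716)), 0.06)
  expect_equal(compute_tef(152, 152), 1)
  expect_equal(compute_tef(2820, 12660), 2820 / 12660)
  expect_equal(format_tef(compute_tef(2820, 7380)), 0.38)
  expect_equal(format_tef(compute_tef(2820, 12660)), 0.22)
  expect_error(compute_tef(0, 10), "positive")
  expect_error(compute_tef(10, -1), "positive")

  tt <- default_tef_table()
  expect_equal(tt$acute_tef[tt$compound == "IMI"], 1)
  expect_equal(tt$chronic_tef[tt$compound == "IMI"], 1)
  expect_true(all(tt$acute_tef > 0 & tt$acute_tef <= 1))
  expect_true(all(tt$chronic_tef > 0 & tt$chronic_tef <= 1))
})

test_that("usage interpolation fills survey gaps by the stated rules", {
  usage <- data.frame(region_id = "R1", survey_year = c(1994L, 1996L),
                      crop = "wheat", compound = "IMI", mass_kg = c(4, 8))
  mean_fill <- interpolate_usage(usage, "mean")
  expect_equal(mean_fill$mass_kg[mean_fill$year == 1995], 6)
  stepped <- interpolate_usage(usage, "stepped")
  expect_equal(stepped$mass_kg[stepped$year == 1995], 4)
  # surveyed years pass through unchanged
  expect_equal(mean_fill$mass_kg[mean_fill$year %in% c(1994, 1996)], c(4, 8))

  # constant series stays constant under both rules
  const <- data.frame(region_id = "R1", survey_year = seq(1994L, 2002L, 2L),
                      crop = "wheat", compound = "IMI", mass_kg = 7)
  for (m in c("mean", "stepped")) {
    expect_equal(interpolate_usage(const, m)$mass_kg, rep(7, 9))
  }

  # trailing years beyond the last survey fall back to the stepped rule
  trail <- interpolate_usage(usage, "mean", years = 1994:1997)
  expect_equal(trail$mass_kg[trail$year == 1997], 8)
  # no preceding survey to fill from
  expect_error(interpolate_usage(usage, "mean", years = 1993:1996), "preceding")

  # a combination absent from one survey year counts as zero mass there
  gappy <- data.frame(region_id = "R1", survey_year = c(1994L, 1998L),
                      crop = "wheat", compound = c("IMI", "CTD"),
                      mass_kg = c(4, 6))
  gf <- interpolate_usage(gappy, "mean")
  expect_equal(gf$mass_kg[gf$compound == "IMI" & gf$year == 1998], 0)
  expect_equal(gf$mass_kg[gf$compound == "IMI" & gf$year == 1996], 2)
})

test_that("crop-area interpolation honours the per-crop fill rules", {
  grid <- data.frame(grid_id = "G001", region_id = "R1",
                     year = c(1994L, 1996L), crop = "wheat",
                     area_ha = c(10, 20))
  lin <- interpolate_crop_areas(grid, years = 1994:1996,
                                excluded_years = integer())
  expect_equal(lin$area_ha[lin$year == 1995], 15)

  # single grid holding the whole region: JSA total passes straight through
  jsa <- data.frame(region_id = "R1", year = 1995L, crop = "wheat",
                    area_ha = 37)
  reg <- interpolate_crop_areas(grid, jsa, years = 1994:1996,
                                excluded_years = integer(),
                                default_method = "regional_jsa")
  expect_equal(reg$area_ha[reg$year == 1995], 37)

  # two grids split the JSA total by their anchor-year shares
  grid2 <- data.frame(grid_id = c("G001", "G002"), region_id = "R1",
                      year = 1994L, crop = "wheat", area_ha = c(30, 70))
  grid2 <- rbind(grid2, transform(grid2, year = 1996L))
  jsa2 <- data.frame(region_id = "R1", year = 1995L, crop = "wheat",
                     area_ha = 50)
  reg2 <- interpolate_crop_areas(grid2, jsa2, years = 1994:1996,
                                 excluded_years = integer(),
                                 default_method = "regional_jsa")
  got <- reg2[reg2$year == 1995, ]
  expect_equal(got$area_ha[order(got$grid_id)], c(0.3, 0.7) * 50)

  # excluded years are emitted as absent and flagged
  excl <- interpolate_crop_areas(grid, jsa, years = 1994:1996,
                                 excluded_years = 1995L)
  expect_false(1995 %in% excl$year)
  expect_equal(attr(excl, "excluded_years"), 1995L)

  # absent JSA totals degrade to a warning, year left absent
  expect_warning(
    no_jsa <- interpolate_crop_areas(
      grid2, data.frame(region_id = "R2", year = 1995L, crop = "wheat",
                        area_ha = 1),
      years = 1994:1996, excluded_years = integer(),
      default_method = "regional_jsa"),
    "JSA total absent")
  expect_false(1995 %in% no_jsa$year)

  expect_error(
    interpolate_crop_areas(grid[1, ], years = 1994:1996,
                           excluded_years = integer()),
    ">= 2 census years")
})

test_that("allocation implements the share formula and conserves mass", {
  # one grid holds the entire regional crop
  one <- data.frame(grid_id = "G001", region_id = "R1", year = 2000L,
                    crop = "wheat", area_ha = 55)
  use <- data.frame(region_id = "R1", year = 2000L, crop = "wheat",
                    compound = "IMI", mass_kg = 10)
  expect_equal(allocate_usage(one, use)$mass_kg, 10)

  # zero cropped area in a grid receives nothing; 30/70 ha split 5 kg 1.5/3.5
  three <- data.frame(grid_id = c("G001", "G002", "G003"), region_id = "R1",
                      year = 2000L, crop = "wheat", area_ha = c(30, 70, 0))
  use5 <- transform(use, mass_kg = 5)
  got <- allocate_usage(three, use5)
  expect_equal(got$mass_kg[match(c("G001", "G002"), got$grid_id)], c(1.5, 3.5))
  expect_true(!"G003" %in% got$grid_id || got$mass_kg[got$grid_id == "G003"] == 0)

  # usage with zero regional area: hard error by default, droppable
  zero <- transform(three, area_ha = 0)
  expect_error(allocate_usage(zero, use5), "zero")
  expect_warning(dropped <- allocate_usage(zero, use5, zero_area_action = "drop"),
                 "dropped")
  expect_equal(nrow(dropped), 0L)
})

test_that("allocation matches a brute-force evaluation on small instances", {
  for (seed in 1:5) {
    set.seed(seed)
    n_grids <- sample(2:5, 1)
    grids <- sprintf("G%03d", seq_len(n_grids))
    areas <- expand.grid(grid_id = grids, year = 2000:2002,
                         crop = c("wheat", "osr"), KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
    areas$region_id <- "R1"
    areas$area_ha <- rgamma(nrow(areas), 2, 0.02)
    usage <- expand.grid(region_id = "R1", year = 2000:2002,
                         crop = c("wheat", "osr"), compound = c("IMI", "CTD"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    usage$mass_kg <- rgamma(nrow(usage), 2, 0.5)
    got <- allocate_usage(areas, usage)
    oracle <- brute_force_allocate(areas, usage)
    merged <- merge(got, oracle, by = c("grid_id", "year", "compound"))
    expect_equal(nrow(merged), nrow(oracle))
    expect_equal(merged$mass_kg.x, merged$mass_kg.y, tolerance = 1e-12)
  }
})

test_that("increasing a grid's area never decreases its allocated mass", {
  base <- data.frame(grid_id = c("G001", "G002"), region_id = "R1",
                     year = 2000L, crop = "wheat", area_ha = c(30, 70))
  use <- data.frame(region_id = "R1", year = 2000L, crop = "wheat",
                    compound = "IMI", mass_kg = 5)
  before <- allocate_usage(base, use)
  for (bump in c(1, 10, 100)) {
    grown <- base
    grown$area_ha[1] <- grown$area_ha[1] + bump
    after <- allocate_usage(grown, use)
    expect_gte(after$mass_kg[after$grid_id == "G001"],
               before$mass_kg[before$grid_id == "G001"])
  }
})

test_that("TEF weighting scales per-compound masses and preserves ordering", {
  tefs <- default_tef_table()
  m <- function(cmp, kg) data.frame(grid_id = "G001", region_id = "R1",
                                    year = 2000L, compound = cmp, mass_kg = kg,
                                    stringsAsFactors = FALSE)
  expect_equal(apply_tef(m("IMI", 2), tefs, "acute")$tef_adjusted_kg, 2)
  expect_equal(apply_tef(m("CTD", 10), tefs, "acute")$tef_adjusted_kg, 0.76)
  mixed <- do.call(rbind, list(m("IMI", 1), m("CTD", 1), m("THX", 1)))
  expect_equal(apply_tef(mixed, tefs, "chronic")$tef_adjusted_kg,
               1 + 2820 / 7380 + 2820 / 12660)
  # per-compound masses survive alongside the weighted total
  wide <- apply_tef(mixed, tefs, "acute")
  expect_equal(unlist(wide[, c("IMI", "CTD", "THX")], use.names = FALSE),
               c(1, 1, 1))
  expect_error(apply_tef(m("XYZ", 1), tefs, "acute"), "XYZ")

  # acute-weighted <= chronic-weighted <= raw for any mass vector
  for (seed in 1:10) {
    set.seed(seed)
    mm <- do.call(rbind, list(m("IMI", rgamma(1, 2)), m("CTD", rgamma(1, 2)),
                              m("THX", rgamma(1, 2))))
    acute <- apply_tef(mm, tefs, "acute")$tef_adjusted_kg
    chronic <- apply_tef(mm, tefs, "chronic")$tef_adjusted_kg
    expect_lte(acute, chronic)
    expect_lte(chronic, sum(mm$mass_kg))
  }
})
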