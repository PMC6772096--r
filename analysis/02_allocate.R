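# Stage 2: disaggregate regional usage to the 5x5 km grid.
#
# Survey-gap years are filled with the mean of the bracketing surveys,
# missing census years from the regional June-survey totals; each region's
# mass is then shared across its grid squares in proportion to cropped
# area and weighted by the acute toxicity equivalency factors.

source("analysis/00_config.R")

cfg <- analysis_config()
crop_areas <- read.csv(file.path(BUNDLE_DIR, "crop_areas.csv"))
usage <- read.csv(file.path(BUNDLE_DIR, "usage.csv"))
jsa <- read.csv(file.path(BUNDLE_DIR, "jsa.csv"))
tefs <- tef_table(read.csv(file.path(BUNDLE_DIR, "tef.csv")))

exposure <- neonicbirds:::compute_exposure(crop_areas, usage, jsa, tefs, cfg)
write.csv(exposure, file.path("results", "grid_exposure.csv"), row.names = FALSE)

applied <- exposure$tef_adjusted_kg[exposure$tef_adjusted_kg > 0]
cat(sprintf("Exposure surface: %d grid squares x %d years (1998 absent: no cropping data)\n",
            length(unique(exposure$grid_id)), length(unique(exposure$year))))
cat(sprintf("TEF-adjusted application per grid-year: median %.2f kg, max %.2f kg\n",
            median(applied), max(applied)))

# conservation audit: allocated mass must equal the surveyed regional mass
annual <- interpolate_usage(usage, method = cfg$usage_interpolation)
annual <- annual[annual$year %in% unique(exposure$year), ]
alloc <- neonicbirds:::check_columns(
  read.csv(file.path("results", "grid_exposure.csv")),
  c("grid_id", "region_id", "year"), "grid_exposure.csv")
comp_cols <- intersect(unique(annual$compound), names(alloc))
got <- aggregate(alloc[comp_cols], alloc[c("region_id", "year")], sum)
want <- aggregate(mass_kg ~ region_id + year, data = annual, sum)
m <- merge(got, want, by = c("region_id", "year"))
err <- max(abs(rowSums(m[comp_cols]) - m$mass_kg) / m$mass_kg)
cat(sprintf("Allocation conservation: max relative error %.2e\n", err))
stopifnot(err < 1e-9)
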