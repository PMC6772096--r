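# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# A small exposure surface: gamma-distributed TEF-adjusted kg per grid x year.
make_exposure <- function(n_grids, years, seed = 1, mean_kg = 2) {
  set.seed(seed)
  expo <- expand.grid(grid_id = sprintf("G%03d", seq_len(n_grids)),
                      year = years, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  expo$tef_adjusted_kg <- rgamma(nrow(expo), shape = 2, rate = 2 / mean_kg)
  expo
}

# Site layout: `sites_per_grid` sites on each of `n_grids` grids spread over
# `n_regions` regions.
make_layout <- function(n_grids, sites_per_grid = 2, n_regions = 2) {
  data.frame(
    site_id = sprintf("S%04d", seq_len(n_grids * sites_per_grid)),
    grid_id = rep(sprintf("G%03d", seq_len(n_grids)), each = sites_per_grid),
    region_id = rep(sprintf("R%d", rep_len(seq_len(n_regions), n_grids)),
                    each = sites_per_grid),
    stringsAsFactors = FALSE)
}

# One simulated dataset drawn from the generative count model (a single
# realised count per site x year), prepared and assembled into a design.
make_design <- function(exposure, layout, params, baseline_year) {
  vis <- simulate_counts(exposure, layout, params, baseline_year, n_visits = 1)
  counts <- prepare_counts(vis, excluded_years = integer())
  build_design(counts, exposure, baseline_year)
}

# Independent brute-force evaluation of the allocation share formulas,
# looping row by row: Z = 100 x / y, B = (A / 100) Z, summed over crops.
brute_force_allocate <- function(grid_areas, usage) {
  out <- list()
  for (i in seq_len(nrow(usage))) {
    u <- usage[i, ]
    sel <- grid_areas$region_id == u$region_id & grid_areas$year == u$year &
      grid_areas$crop == u$crop
    g <- grid_areas[sel, ]
    y <- sum(g$area_ha)
    for (j in seq_len(nrow(g))) {
      z <- 100 * g$area_ha[j] / y
      b <- (u$mass_kg / 100) * z
      out[[length(out) + 1L]] <- data.frame(
        grid_id = g$grid_id[j], year = u$year, compound = u$compound,
        mass_kg = b, stringsAsFactors = FALSE)
    }
  }
  agg <- stats::aggregate(mass_kg ~ grid_id + year + compound,
                          data = do.call(rbind, out), FUN = sum)
  agg[order(agg$grid_id, agg$year, agg$compound), ]
}
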