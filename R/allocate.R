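# Spatial disaggregation of regional pesticide usage to grid squares.
#
# The usage surveys report mass applied per region x crop x compound in
# survey years only (biennial cadence); the agricultural census reports
# cropped area per 5x5 km grid square, with runs of missing years filled
# from regional (or national) June-survey totals. Allocation shares each
# region's mass across its grid squares in proportion to cropped area:
#
#   Z = 100 * x / y       grid share (%) of the region's crop
#   B = (A / 100) * Z     mass of one compound allocated to the grid, one crop
#   C = sum over crops B  total mass per grid square
#
# so mass is conserved exactly within each region x crop x compound x year.

#' Fill non-survey years in a regional usage table
#'
#' Usage surveys run on a fixed cadence (biennial in the packaged study
#' design); intervening years are filled per region x crop x compound either
#' with the arithmetic mean of the nearest preceding and following surveyed
#' values (`method = "mean"`, the primary rule) or by carrying the preceding
#' surveyed value forward (`method = "stepped"`, the sensitivity rule).
#' Surveyed years pass through unchanged. Region x crop x compound
#' combinations absent from a survey year are treated as zero mass in that
#' year. Years after the last survey are filled by the stepped rule under
#' both methods (there is no following value to average with).
#'
#' @param usage Data frame with columns `region_id`, `survey_year`, `crop`,
#'   `compound`, `mass_kg` (survey years only).
#' @param method `"mean"` or `"stepped"`.
#' @param years Optional integer vector of years the output must cover;
#'   defaults to `min(survey_year):max(survey_year)`. Requesting a year
#'   before the first survey is an error (no preceding value exists).
#' @return Data frame `region_id, year, crop, compound, mass_kg` covering
#'   every requested year.
#' @export
interpolate_usage <- function(usage, method = c("mean", "stepped"), years = NULL) {
  method <- match.arg(method)
  check_columns(usage, c("region_id", "survey_year", "crop", "compound", "mass_kg"),
                "usage")
  if (any(usage$mass_kg < 0)) stop("usage mass_kg must be non-negative", call. = FALSE)
  survey_years <- sort(unique(usage$survey_year))
  years <- sort(unique(as.integer(years %||% (min(survey_years):max(survey_years)))))
  if (min(years) < min(survey_years)) {
    stop(sprintf("year %d precedes the first survey (%d): no preceding value to fill from",
                 min(years), min(survey_years)), call. = FALSE)
  }

  combos <- unique(usage[, c("region_id", "crop", "compound")])
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sel <- usage$region_id == combos$region_id[i] &
      usage$crop == combos$crop[i] & usage$compound == combos$compound[i]
    # absent survey-year entries for this combination count as zero mass
    mass_at <- stats::setNames(rep(0, length(survey_years)), survey_years)
    mass_at[as.character(usage$survey_year[sel])] <- usage$mass_kg[sel]
    filled <- vapply(years, function(y) {
      if (y %in% survey_years) return(mass_at[[as.character(y)]])
      prev <- max(survey_years[survey_years < y])
      nxt <- survey_years[survey_years > y]
      if (method == "stepped" || length(nxt) == 0L) {
        mass_at[[as.character(prev)]]
      } else {
        (mass_at[[as.character(prev)]] + mass_at[[as.character(min(nxt))]]) / 2
      }
    }, numeric(1))
    out[[i]] <- data.frame(region_id = combos$region_id[i], year = years,
                           crop = combos$crop[i], compound = combos$compound[i],
                           mass_kg = filled, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Complete a grid-level crop-area table across missing census years
#'
#' Three fill rules, selectable per crop: `"linear"` interpolates each grid
#' x crop series between its bracketing available census years;
#' `"regional_jsa"` gives the grid its share of the regional crop in the
#' nearest available census year, scaled to that year's regional June-survey
#' total; `"national_jsa"` does the same against national totals (rows with
#' `region_id == "NATIONAL"` in `jsa`). Years in `excluded_years` are left
#' absent from the output (no survey totals exist to fill them); they are
#' recorded in the `excluded_years` attribute of the result.
#'
#' @param grid_areas Data frame `grid_id, region_id, year, crop, area_ha`
#'   covering the available census years.
#' @param jsa Data frame `region_id, year, crop, area_ha` of June-survey
#'   totals (`region_id = "NATIONAL"` for national rows).
#' @param methods Named character vector mapping crop label to fill rule;
#'   crops not named fall back to `default_method`.
#' @param years Integer vector of years the output should cover.
#' @param excluded_years Years emitted as absent (default 1998, the year
#'   with neither census nor survey totals).
#' @param default_method Fill rule for crops not in `methods`.
#' @return Completed `grid_id, region_id, year, crop, area_ha` table with an
#'   `excluded_years` attribute.
#' @export
interpolate_crop_areas <- function(grid_areas, jsa = NULL, methods = character(),
                                   years, excluded_years = 1998L,
                                   default_method = "linear") {
  check_columns(grid_areas, c("grid_id", "region_id", "year", "crop", "area_ha"),
                "crop_areas")
  if (any(grid_areas$area_ha < 0)) stop("area_ha must be non-negative", call. = FALSE)
  years <- sort(unique(as.integer(years)))
  fill_years <- setdiff(years, excluded_years)
  pieces <- list(grid_areas[grid_areas$year %in% fill_years, ])
  for (crop in unique(grid_areas$crop)) {
    method <- if (crop %in% names(methods)) methods[[crop]] else default_method
    method <- match.arg(method, c("linear", "regional_jsa", "national_jsa"))
    crop_rows <- grid_areas[grid_areas$crop == crop, ]
    missing_years <- setdiff(fill_years, unique(crop_rows$year))
    if (length(missing_years) == 0L) next
    pieces[[length(pieces) + 1L]] <- switch(
      method,
      linear = fill_linear(crop_rows, crop, missing_years),
      regional_jsa = fill_jsa(crop_rows, jsa, crop, missing_years, national = FALSE),
      national_jsa = fill_jsa(crop_rows, jsa, crop, missing_years, national = TRUE)
    )
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$crop, out$grid_id, out$year), ]
  rownames(out) <- NULL
  attr(out, "excluded_years") <- intersect(years, excluded_years)
  out
}

# Straight-line interpolation per grid between bracketing census years.
fill_linear <- function(crop_rows, crop, missing_years) {
  out <- lapply(split(crop_rows, crop_rows$grid_id), function(g) {
    if (nrow(g) < 2L) {
      stop(sprintf("linear interpolation for crop '%s', grid '%s' needs >= 2 census years",
                   crop, g$grid_id[1]), call. = FALSE)
    }
    inside <- missing_years[missing_years > min(g$year) & missing_years < max(g$year)]
    if (length(inside) < length(missing_years)) {
      stop(sprintf("no bracketing census years for crop '%s', grid '%s', year(s) %s",
                   crop, g$grid_id[1],
                   paste(setdiff(missing_years, inside), collapse = ", ")),
           call. = FALSE)
    }
    data.frame(grid_id = g$grid_id[1], region_id = g$region_id[1],
               year = missing_years,
               crop = crop,
               area_ha = stats::approx(g$year, g$area_ha, xout = missing_years)$y,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Share-of-region (or share-of-nation) in the nearest census year, scaled to
# that year's survey total. Ties between equally near census years resolve
# to the earlier year.
fill_jsa <- function(crop_rows, jsa, crop, missing_years, national) {
  if (is.null(jsa)) stop("JSA totals are required for JSA-based interpolation", call. = FALSE)
  check_columns(jsa, c("region_id", "year", "crop", "area_ha"), "jsa")
  avail <- sort(unique(crop_rows$year))
  out <- list()
  for (y in missing_years) {
    anchor <- avail[which.min(abs(avail - y))]
    anc <- crop_rows[crop_rows$year == anchor, ]
    denom_by <- if (national) rep("NATIONAL", nrow(anc)) else anc$region_id
    denom <- tapply(anc$area_ha, denom_by, sum)
    jsa_y <- jsa[jsa$year == y & jsa$crop == crop, ]
    if (national) jsa_y <- jsa_y[jsa_y$region_id == "NATIONAL", ]
    total <- stats::setNames(jsa_y$area_ha, jsa_y$region_id)
    key <- if (national) rep("NATIONAL", nrow(anc)) else anc$region_id
    if (!all(key %in% names(total))) {
      warning(sprintf("JSA total absent for crop '%s' in %d; year left absent", crop, y),
              call. = FALSE)
      next
    }
    share <- anc$area_ha / unname(denom[key])
    share[is.nan(share)] <- 0
    out[[length(out) + 1L]] <- data.frame(
      grid_id = anc$grid_id, region_id = anc$region_id, year = y, crop = crop,
      area_ha = share * unname(total[key]), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Allocate regional usage mass to grid squares in proportion to cropped area
#'
#' Implements the share formula above: each grid receives
#' `A * x / y` kg of a compound, where `x` is its cropped area, `y` the
#' regional cropped area and `A` the regional mass for that crop. Results
#' are summed over crops to per-grid, per-year, per-compound masses; mass is
#' conserved exactly within every region x crop x compound x year.
#'
#' @param grid_areas Completed crop-area table (`grid_id, region_id, year,
#'   crop, area_ha`); every year carrying usage must be present.
#' @param usage Annual usage table (`region_id, year, crop, compound,
#'   mass_kg`), e.g. from [interpolate_usage()].
#' @param zero_area_action What to do when a region x crop x year carries
#'   mass but has zero cropped area: `"error"` (default — silent mass loss
#'   would break conservation) or `"drop"` with a warning.
#' @return Data frame `grid_id, region_id, year, compound, mass_kg`.
#' @export
allocate_usage <- function(grid_areas, usage, zero_area_action = c("error", "drop")) {
  zero_area_action <- match.arg(zero_area_action)
  check_columns(grid_areas, c("grid_id", "region_id", "year", "crop", "area_ha"),
                "crop_areas")
  check_columns(usage, c("region_id", "year", "crop", "compound", "mass_kg"), "usage")

  key <- function(...) do.call(paste, c(list(...), sep = "\r"))
  region_total <- tapply(grid_areas$area_ha,
                         key(grid_areas$region_id, grid_areas$year, grid_areas$crop),
                         sum)
  usage_key <- key(usage$region_id, usage$year, usage$crop)
  y_tot <- region_total[usage_key]
  bad <- usage$mass_kg > 0 & (is.na(y_tot) | y_tot <= 0)
  if (any(bad)) {
    msg <- sprintf("usage mass with zero/absent cropped area in %d region x crop x year cell(s), e.g. region %s, crop %s, year %d",
                   sum(bad), usage$region_id[bad][1], usage$crop[bad][1],
                   usage$year[bad][1])
    if (zero_area_action == "error") stop(msg, call. = FALSE)
    warning(paste(msg, "- dropped"), call. = FALSE)
    usage <- usage[!bad, ]
  }
  usage <- usage[usage$mass_kg > 0, ]
  if (nrow(usage) == 0L) {
    return(data.frame(grid_id = character(), region_id = character(),
                      year = integer(), compound = character(),
                      mass_kg = numeric(), stringsAsFactors = FALSE))
  }

  m <- merge(grid_areas, usage, by = c("region_id", "year", "crop"))
  y_tot <- region_total[key(m$region_id, m$year, m$crop)]
  z_pct <- 100 * m$area_ha / unname(y_tot)       # grid share of regional crop (%)
  m$alloc_kg <- (m$mass_kg / 100) * z_pct        # per-crop allocated mass

  agg <- stats::aggregate(alloc_kg ~ grid_id + region_id + year + compound,
                          data = m, FUN = sum)
  names(agg)[names(agg) == "alloc_kg"] <- "mass_kg"
  agg <- agg[order(agg$grid_id, agg$year, agg$compound), ]
  rownames(agg) <- NULL
  agg
}

#' Weight per-compound grid masses by toxicity equivalency
#'
#' Converts the long per-compound allocation into one row per grid x year
#' with per-compound mass columns and their TEF-weighted sum,
#' `tef_adjusted_kg = sum over compounds TEF * mass`. The acute basis is the
#' primary analysis; the chronic basis is the sensitivity analysis.
#'
#' @param grid_masses Output of [allocate_usage()].
#' @param tefs TEF table from [tef_table()] / [default_tef_table()].
#' @param mode `"acute"` or `"chronic"`.
#' @return Data frame `grid_id, region_id, year, <one column per compound>,
#'   tef_adjusted_kg`.
#' @export
apply_tef <- function(grid_masses, tefs, mode = c("acute", "chronic")) {
  mode <- match.arg(mode)
  check_columns(tefs, c("compound", "acute_tef", "chronic_tef"), "tef")
  if (nrow(grid_masses) == 0L) {
    return(data.frame(grid_id = character(), region_id = character(),
                      year = integer(), tef_adjusted_kg = numeric(),
                      stringsAsFactors = FALSE))
  }
  check_columns(grid_masses, c("grid_id", "region_id", "year", "compound", "mass_kg"),
                "grid_masses")
  tef_col <- paste0(mode, "_tef")
  tef <- stats::setNames(tefs[[tef_col]], tefs$compound)
  grid_masses$tef_kg <- grid_masses$mass_kg *
    lookup(grid_masses$compound, tef, "compound")

  wide <- stats::reshape(
    grid_masses[, c("grid_id", "region_id", "year", "compound", "mass_kg")],
    idvar = c("grid_id", "region_id", "year"), timevar = "compound",
    direction = "wide")
  names(wide) <- sub("^mass_kg\\.", "", names(wide))
  comp_cols <- setdiff(names(wide), c("grid_id", "region_id", "year"))
  wide[comp_cols][is.na(wide[comp_cols])] <- 0

  adj <- stats::aggregate(tef_kg ~ grid_id + region_id + year,
                          data = grid_masses, FUN = sum)
  out <- merge(wide, adj, by = c("grid_id", "region_id", "year"))
  names(out)[names(out) == "tef_kg"] <- "tef_adjusted_kg"
  out <- out[order(out$grid_id, out$year), ]
  rownames(out) <- NULL
  out
}
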