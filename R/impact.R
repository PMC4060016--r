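# Foraging intensity and the per-pixel prey-consumption (impact) surface.

#' Foraging success rate from its observational components
#'
#' Prey captured per nest per hour is the product of the forager return
#' ("traffic") rate per minute, the fraction of returning foragers carrying
#' material, and the fraction of carried material that is prey, scaled to an
#' hour: `60 * r * m * q`. With the field-study means (r = 0.33/min,
#' m = 0.30, q = 0.75) this is 4.455, reported as 4.5 prey/nest/hour; the
#' component ranges bracket it at 2.4-8.4.
#'
#' @param traffic_rate r, forager returns per minute (>= 0).
#' @param prop_material m, fraction of returns carrying material, in `[0,1]`.
#' @param prop_prey q, fraction of material that is prey, in `[0,1]`.
#' @return prey per nest per hour, unrounded (round to 1 dp for reporting).
#' @examples
#' foraging_success_rate(0.33, 0.30, 0.75)  # 4.455 -> reported 4.5
#' @export
foraging_success_rate <- function(traffic_rate = 0.33, prop_material = 0.30,
                                  prop_prey = 0.75) {
  vals <- c(traffic_rate, prop_material, prop_prey)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("validation error: components must be finite and non-negative")
  if (prop_material > 1 || prop_prey > 1)
    stop("validation error: proportions must not exceed 1")
  60 * traffic_rate * prop_material * prop_prey
}

#' Mean and range of an observational component, with outlier exclusion
#'
#' @param observations numeric per-site values.
#' @param exclusions values to drop as outliers (logged).
#' @return list with `mean` and `range` (min, max) of the retained values.
#' @export
component_means <- function(observations, exclusions = numeric(0)) {
  keep <- !(observations %in% exclusions)
  if (length(exclusions) && any(!keep))
    log_info("component_means: excluded %d outlier value(s): %s",
             sum(!keep), paste(observations[!keep], collapse = ", "))
  x <- observations[keep]
  if (!length(x)) stop("input error: all values excluded")
  list(mean = mean(x), range = c(min(x), max(x)))
}

#' Seasonal bright-sunshine foraging hours per cell
#'
#' Paper wasps forage neither at night nor in rain, so the time available to
#' forage is taken as bright-sunshine hours: in-season hours whose radiation
#' is at or above the bright-sunshine threshold (default 0.432 MJ m-2 per
#' hour, i.e. the 120 W m-2 WMO bright-sunshine definition). Hours exactly
#' at the threshold count (closed bound). Night hours have radiation ~0 and
#' are excluded by the same rule.
#'
#' @param sunshine a `si_sunshine` stack ([generate_sunshine_stack()] or
#'   [sunshine_stack()]).
#' @param bright_threshold threshold override in MJ m-2 per hour (default:
#'   the stack's own).
#' @return list of class `si_hours`: `layer` ([si_raster()] of hours) and
#'   `bright_threshold`.
#' @export
seasonal_foraging_hours <- function(sunshine, bright_threshold = NULL) {
  stopifnot(inherits(sunshine, "si_sunshine"))
  thr <- bright_threshold %||% sunshine$bright_threshold
  hours <- apply(sunshine$radiation >= thr, c(1, 2), sum)
  structure(list(layer = si_raster(hours, sunshine$grid,
                                   name = "foraging_hours", units = "h/season"),
                 bright_threshold = thr),
            class = "si_hours")
}

#' Per-pixel prey consumption over a season
#'
#' The step-wise combination: a cell of land-cover class `c` inside the
#' suitable distribution holds `cell_area_ha * psi_c * D_c` expected nests
#' (unrounded), each consuming `F` prey per foraging hour, over that cell's
#' seasonal foraging hours:
#' `prey = nests * F * hours`. Cells outside the mask, or of classes with
#' zero density, consume nothing.
#'
#' @param mask suitable-mask [si_raster()] (nonzero = suitable).
#' @param landcover integer-coded land-cover [si_raster()], aligned.
#' @param estimates density-estimate data.frame (`class`, `occupancy`,
#'   `density`).
#' @param success_rate F, prey per nest per hour (use the unrounded value).
#' @param hours a `si_hours` layer from [seasonal_foraging_hours()], aligned.
#' @param class_table the class vocabulary.
#' @return list of class `si_impact`: `layer` (prey/pixel/season),
#'   `nests` ([si_raster()] of expected nests per pixel), `hours`,
#'   `success_rate`.
#' @export
impact_surface <- function(mask, landcover, estimates, success_rate, hours,
                           class_table = default_class_table()) {
  stop_if_misaligned(mask, landcover, "mask and land cover")
  stop_if_misaligned(mask, hours$layer, "mask and hours")
  if (!is.finite(success_rate) || success_rate < 0)
    stop("validation error: success rate must be finite and non-negative")
  grid <- mask$grid
  codes <- class_table$code[landcover$values]
  ei <- match(codes, estimates$class)
  unmatched <- unique(codes[is.na(ei) & !is.na(codes)])
  if (length(unmatched))
    log_info("impact_surface: class(es) without estimate treated as zero: %s",
             paste(unmatched, collapse = ", "))
  psi <- ifelse(is.na(ei), 0, estimates$occupancy[ei])
  dens <- ifelse(is.na(ei), 0, estimates$density[ei])
  inside <- mask$values != 0 & !mask$nodata_mask
  nests <- matrix(cell_area_ha(grid) * psi * dens, grid$n_rows, grid$n_cols)
  nests[!inside] <- 0
  prey <- nests * success_rate * hours$layer$values
  nodata <- mask$nodata_mask | landcover$nodata_mask | hours$layer$nodata_mask
  structure(list(
    layer = si_raster(ifelse(nodata, NaN, prey), grid, nodata_mask = nodata,
                      name = "impact", units = "prey/pixel/season"),
    nests = si_raster(ifelse(nodata, NaN, nests), grid, nodata_mask = nodata,
                      name = "nests", units = "nests/pixel"),
    hours = hours, success_rate = success_rate),
    class = "si_impact")
}

#' National prey-consumption totals
#'
#' Two routes to the seasonal national prey budget: the raster total (sum of
#' the impact surface over cells) and the table-based estimate
#' `total_nests * F * mean_hours`. With spatially uniform foraging hours and
#' areas derived from the same mask the two agree up to the table's flooring
#' convention.
#'
#' @param impact a `si_impact` from [impact_surface()] (or NULL to report
#'   only the table-based estimate).
#' @param table an [extrapolate()] result (or NULL for raster-only totals).
#' @param success_rate F used for the table-based estimate.
#' @param mean_hours seasonal foraging hours used for the table-based
#'   estimate (e.g. the mean of within-distribution reference values,
#'   [reference_sunshine_hours()]).
#' @return list: `raster_total_prey`, `table_total_nests`,
#'   `table_total_prey`, `table_total_prey_billion`, `success_rate`,
#'   `mean_hours`.
#' @export
national_totals <- function(impact = NULL, table = NULL, success_rate,
                            mean_hours) {
  raster_total <- if (!is.null(impact)) {
    sum(impact$layer$values[!impact$layer$nodata_mask])
  } else NA_real_
  nests <- if (!is.null(table)) extrapolation_totals(table)$total_nests
           else NA_real_
  table_total <- nests * success_rate * mean_hours
  list(raster_total_prey = raster_total,
       table_total_nests = nests,
       table_total_prey = table_total,
       table_total_prey_billion = table_total / 1e9,
       success_rate = success_rate, mean_hours = mean_hours)
}

#' Reference seasonal sunshine hours at ten New Zealand locations
#'
#' Bright-sunshine hour totals (annual, and the February-April wasp season)
#' at ten weather stations spanning the country, with a flag for whether the
#' station lies within the species' modelled potential distribution. The
#' mean seasonal value over within-distribution stations (~540 h) is the
#' standard choice of `mean_hours` for the table-based national prey budget.
#'
#' @return data.frame with columns `latitude`, `location`, `annual_hours`,
#'   `season_hours`, `within_distribution`.
#' @export
reference_sunshine_hours <- function() {
  data.frame(
    latitude = c(-36.85, -37.77, -37.67, -39.49, -40.36, -41.30, -43.47,
                 -45.02, -45.86, -46.41),
    location = c("Auckland", "Hamilton", "Tauranga", "Napier",
                 "Palmerston North", "Wellington", "Christchurch",
                 "Queenstown", "Dunedin", "Invercargill"),
    annual_hours = c(1949, 1954, 2169, 2161, 1852, 1986, 2040, 1927, 1594, 1649),
    season_hours = c(519, 529, 576, 550, 526, 553, 528, 545, 407, 421),
    within_distribution = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                            NA, FALSE, FALSE),
    stringsAsFactors = FALSE)
}
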