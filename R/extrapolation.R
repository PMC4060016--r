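# National extrapolation: class areas within the suitable distribution,
# combined with per-class density/occupancy into the summary table.

#' Land-cover class areas within the suitable distribution
#'
#' Hectares of each class among cells where the suitability mask is true:
#' `cell_area_ha * number of masked cells of the class`.
#'
#' @param landcover integer-coded land-cover [si_raster()].
#' @param mask suitable-mask [si_raster()] (nonzero = suitable), aligned
#'   with `landcover`.
#' @param class_table the class vocabulary (default [default_class_table()]).
#' @return named numeric vector: class code -> hectares (only classes
#'   present under the mask appear).
#' @export
class_area <- function(landcover, mask, class_table = default_class_table()) {
  stop_if_misaligned(landcover, mask, "land cover and mask")
  inside <- mask$values != 0 & !mask$nodata_mask & !landcover$nodata_mask
  codes <- class_table$code[landcover$values[inside]]
  counts <- table(factor(codes, levels = class_table$code))
  ha <- as.numeric(counts) * cell_area_ha(landcover$grid)
  stats::setNames(ha, class_table$code)[as.numeric(counts) > 0 | FALSE]
}

#' Extrapolate per-class density and occupancy to class areas
#'
#' Row arithmetic uses the *reported* (rounded) occupancy and density and
#' truncates each product toward zero before summing:
#' `occupied_ha = floor(A_c * psi_c)` and
#' `total_nests = floor(A_c * psi_c * D_c)`; the TOTAL row sums the floored
#' row values. Unfloored (continuous) columns are also emitted for
#' downstream raster arithmetic, where no report-rounding applies.
#'
#' @param areas named numeric vector from [class_area()] (class -> ha).
#' @param estimates density-estimate data.frame (rows from
#'   [summarize_plots()] and/or [assign_nominal()]).
#' @param class_table the class vocabulary; classes with area but no
#'   estimate must be categorized `unsuitable` (treated as zero, logged),
#'   otherwise a configuration error is raised.
#' @return data.frame of class `si_extrapolation`: one row per class with
#'   columns `class`, `potential_ha`, `n_plots`, `n_nests`, `occupancy`,
#'   `occupied_ha`, `density`, `total_nests`, `occupied_ha_raw`,
#'   `total_nests_raw`, `provenance`, plus a final TOTAL row.
#' @export
extrapolate <- function(areas, estimates, class_table = default_class_table()) {
  if (anyDuplicated(estimates$class))
    stop("configuration error: duplicate density estimate for class ",
         estimates$class[duplicated(estimates$class)][1])
  classes <- names(areas)
  est_idx <- match(classes, estimates$class)
  missing <- classes[is.na(est_idx)]
  if (length(missing)) {
    cat_of <- class_table$category[match(missing, class_table$code)]
    bad <- missing[is.na(cat_of) | cat_of != "unsuitable"]
    if (length(bad))
      stop("configuration error: no density estimate for suitable class(es): ",
           paste(bad, collapse = ", "))
    log_info("extrapolate: %d unsuitable class(es) with area treated as zero: %s",
             length(missing), paste(missing, collapse = ", "))
  }
  # classes with an estimate but zero area still get a (zero-area) row
  extra <- setdiff(estimates$class, classes)
  all_classes <- c(classes, extra)
  a <- c(areas, stats::setNames(rep(0, length(extra)), extra))
  ei <- match(all_classes, estimates$class)
  psi <- ifelse(is.na(ei), 0, estimates$occupancy[ei])
  dens <- ifelse(is.na(ei), 0, estimates$density[ei])
  rows <- data.frame(
    class = all_classes,
    potential_ha = as.numeric(a),
    n_plots = ifelse(is.na(ei), 0L, estimates$n_plots[ei]),
    n_nests = ifelse(is.na(ei), 0L, estimates$n_nests[ei]),
    occupancy = psi,
    occupied_ha = floor_guard(a * psi),
    density = dens,
    total_nests = floor_guard(a * psi * dens),
    occupied_ha_raw = a * psi,
    total_nests_raw = a * psi * dens,
    provenance = ifelse(is.na(ei), "unsuitable", estimates$provenance[ei]),
    stringsAsFactors = FALSE)
  total <- data.frame(
    class = "TOTAL",
    potential_ha = sum(rows$potential_ha),
    n_plots = sum(rows$n_plots), n_nests = sum(rows$n_nests),
    occupancy = NA_real_,
    occupied_ha = sum(rows$occupied_ha),
    density = NA_real_,
    total_nests = sum(rows$total_nests),
    occupied_ha_raw = sum(rows$occupied_ha_raw),
    total_nests_raw = sum(rows$total_nests_raw),
    provenance = "total", stringsAsFactors = FALSE)
  out <- rbind(rows, total)
  rownames(out) <- NULL
  class(out) <- c("si_extrapolation", class(out))
  out
}

#' Totals row of an extrapolation table
#'
#' @param table an [extrapolate()] result.
#' @return one-row data.frame (the TOTAL row).
#' @export
extrapolation_totals <- function(table) {
  table[table$class == "TOTAL", , drop = FALSE]
}
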