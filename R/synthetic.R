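# Synthetic landscape generator.
#
# Every pipeline stage is testable without external data: environmental
# stacks, land cover, biased occurrences, plot surveys and sunshine stacks
# are all generated from known ground-truth parameters, and all generators
# are pure functions of (parameters, seed).

#' Default land-cover class table
#'
#' A compact stand-in for a national land-cover database: class codes, long
#' names, and their suitability category for the focal wasp. `surveyed`
#' classes get field-survey density estimates; `nominal` classes (possibly
#' suitable but low preference) get the nominal density of 3 nests/ha and
#' occupancy 0.03; `unsuitable` classes get zero. Land-cover rasters store
#' the integer row index of this table.
#'
#' @return data.frame with columns `code`, `name`, `category`.
#' @export
default_class_table <- function() {
  data.frame(
    code = c("HSV", "BUA", "SAS", "FOR", "OVP", "HFV", "TTG",
             "WAT", "BLV", "ART", "CRO", "PAS", "ALP"),
    name = c("Herbaceous saline vegetation", "Built-up area",
             "Scrub and shrubland", "Forest",
             "Orchard vineyard & other perennial crops",
             "Herbaceous freshwater vegetation", "Tall tussock grassland",
             "Water bodies", "Bare or lightly vegetated surfaces",
             "Artificial surfaces", "Cropland", "High-producing grassland",
             "Alpine vegetation"),
    category = c("surveyed", "surveyed", "surveyed", "surveyed",
                 "nominal", "nominal", "nominal",
                 rep("unsuitable", 6)),
    stringsAsFactors = FALSE)
}

# Smoothed-white-noise Gaussian random field on an n_rows x n_cols grid,
# standardized to mean 0 / sd 1. Smoothing is a separable truncated-Gaussian
# convolution implemented as two banded matrix products; `sigma` is the
# correlation length in cells.
gaussian_field <- function(n_rows, n_cols, sigma) {
  noise <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  smooth_field(noise, sigma)
}

smooth_field <- function(m, sigma) {
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-0.5 * (d / sigma)^2)
    k[d > 3 * sigma] <- 0
    k / rowSums(k)  # row-normalized: edges renormalize, no shrink to 0
  }
  sm <- band(nrow(m)) %*% m %*% t(band(ncol(m)))
  (sm - mean(sm)) / stats::sd(sm)
}

#' Environmental layer stack
#'
#' Bundles the six environmental layers the distribution model uses, all
#' aligned on one grid: elevation (m), degree days (degC-day, base 10),
#' annual rainfall (mm/yr), solar radiation (MJ m-2 day-1), and max/min
#' annual temperature (degC).
#'
#' @param layers named list of [si_raster()] layers.
#' @return object of class `si_envstack`.
#' @export
env_stack <- function(layers) {
  stopifnot(length(layers) >= 1, !is.null(names(layers)))
  g <- layers[[1]]$grid
  for (l in layers) stop_if_misaligned(l, g, "environment layers")
  structure(list(grid = g, layers = layers), class = "si_envstack")
}

#' @export
print.si_envstack <- function(x, ...) {
  cat(sprintf("<si_envstack> %d layers on %d x %d grid: %s\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Annual degree-day accumulation above a base temperature
#'
#' Sums the positive excess of each day's mean temperature over the base:
#' `sum(max(0, T_day - base))` across the 365-day year. A year of constant
#' 11 degC at base 10 accumulates 365 degree days.
#'
#' @param daily_mean_temps numeric vector of 365 daily mean temperatures (degC).
#' @param base base temperature in degC (default 10).
#' @return accumulated degree days (degC-day).
#' @export
compute_degree_days <- function(daily_mean_temps, base = 10) {
  if (length(daily_mean_temps) != 365)
    stop("input error: expected 365 daily mean temperatures")
  if (any(!is.finite(daily_mean_temps)))
    stop("input error: non-finite temperature values")
  sum(pmax(0, daily_mean_temps - base))
}

#' Generate a spatially autocorrelated environmental stack
#'
#' Layers are transforms of smoothed-white-noise Gaussian random fields.
#' Elevation drives temperature through a fixed lapse rate (6.5 degC/km), so
#' the realistic inter-layer correlation structure (cold high ground, wet
#' uplands) is present; degree days accumulate a per-cell sinusoidal annual
#' temperature cycle through [compute_degree_days()]. `tmax >= tmin`
#' everywhere and degree days are non-negative by construction.
#'
#' @param grid a [si_grid()].
#' @param seed integer RNG seed; the stack is a pure function of it.
#' @param smoothness correlation length in cells (>= 1).
#' @return an [env_stack()] with layers `elevation`, `degree_days`,
#'   `rainfall`, `solar_radiation`, `tmax`, `tmin`.
#' @export
generate_env_stack <- function(grid, seed = 1, smoothness = 6) {
  if (smoothness < 1) stop("parameter error: smoothness must be >= 1")
  nr <- grid$n_rows; nc <- grid$n_cols
  with_seed(seed, {
    f <- replicate(5, gaussian_field(nr, nc, smoothness), simplify = FALSE)
    lat_gradient <- matrix(seq(1.5, -1.5, length.out = nr), nr, nc)

    elevation <- pmax(450 + 380 * f[[1]], 0)
    tmean <- 14 + 1.5 * f[[2]] + lat_gradient - 6.5 / 1000 * elevation
    spread <- 9 + 1.2 * abs(f[[3]])               # diurnal/annual range, > 0
    tmax <- tmean + spread / 2
    tmin <- tmean - spread / 2
    amp <- 6 + 0.4 * abs(f[[3]])                  # annual cycle amplitude
    cosd <- cos(2 * pi * (seq_len(365) - 15) / 365)
    dd <- vapply(seq_len(nr * nc), function(i) {
      compute_degree_days(tmean[i] + amp[i] * cosd, base = 10)
    }, numeric(1))
    degree_days <- matrix(dd, nr, nc)
    rainfall <- 1100 * exp(0.45 * f[[4]] + 0.0004 * elevation)
    solar <- pmax(14.5 + 1.8 * f[[5]] - 0.8 / 1000 * elevation, 5)

    mk <- function(v, name, units) si_raster(v, grid, name = name, units = units)
    env_stack(list(
      elevation = mk(elevation, "elevation", "m"),
      degree_days = mk(degree_days, "degree_days", "degC-day"),
      rainfall = mk(rainfall, "rainfall", "mm/yr"),
      solar_radiation = mk(solar, "solar_radiation", "MJ m-2 day-1"),
      tmax = mk(tmax, "tmax", "degC"),
      tmin = mk(tmin, "tmin", "degC")))
  })
}

#' Generate a patchy categorical land-cover raster
#'
#' Each class gets a smoothed Gaussian random field; a cell takes the class
#' whose (field + offset) is largest. Offsets are calibrated on the realized
#' fields so empirical class frequencies match the requested weights (within
#' a fraction of a percentage point on grids of 100 x 100 and larger), while
#' the smoothing length controls patch size.
#'
#' @param grid a [si_grid()].
#' @param class_weights named numeric vector: class code -> target frequency
#'   (must sum to 1; codes must exist in `class_table`).
#' @param seed integer RNG seed.
#' @param patchiness patch correlation length in cells (>= 1).
#' @param class_table the class vocabulary (default [default_class_table()]).
#' @return a [si_raster()] of integer codes indexing `class_table$code`.
#' @export
generate_landcover <- function(grid, class_weights, seed = 1, patchiness = 5,
                               class_table = default_class_table()) {
  if (patchiness < 1) stop("parameter error: patchiness must be >= 1")
  w <- class_weights
  if (is.null(names(w)) || !all(names(w) %in% class_table$code))
    stop("schema error: unknown land-cover class code(s): ",
         paste(setdiff(names(w), class_table$code), collapse = ", "))
  if (abs(sum(w) - 1) > 1e-6) stop("parameter error: class weights must sum to 1")
  if (any(w <= 0)) stop("parameter error: class weights must be positive")
  nr <- grid$n_rows; nc <- grid$n_cols
  k <- length(w)
  values <- with_seed(seed, {
    if (k == 1L) {
      matrix(match(names(w), class_table$code), nr, nc)
    } else {
      fields <- lapply(seq_len(k), function(i) gaussian_field(nr, nc, patchiness))
      offsets <- log(w)
      assign_classes <- function(off) {
        best <- matrix(1L, nr, nc); best_v <- fields[[1]] + off[1]
        for (i in seq_len(k)[-1]) {
          v <- fields[[i]] + off[i]
          swap <- v > best_v
          best[swap] <- i; best_v[swap] <- v[swap]
        }
        best
      }
      for (iter in seq_len(300)) {
        cls <- assign_classes(offsets)
        freq <- tabulate(cls, k) / (nr * nc)
        if (max(abs(freq - w)) < 0.002) break
        offsets <- offsets + 0.6 * (log(w) - log(pmax(freq, 1 / (nr * nc))))
      }
      matrix(match(names(w), class_table$code)[cls], nr, nc)
    }
  })
  si_raster(values, grid, name = "landcover", units = "class code")
}

#' Decode a land-cover raster to class codes
#'
#' @param landcover integer-coded [si_raster()] from [generate_landcover()].
#' @param class_table the class vocabulary.
#' @return character matrix of class codes (NA where nodata).
#' @export
landcover_codes <- function(landcover, class_table = default_class_table()) {
  codes <- matrix(class_table$code[landcover$values],
                  landcover$grid$n_rows, landcover$grid$n_cols)
  codes[landcover$nodata_mask] <- NA_character_
  codes
}

# Standardized (landscape mean/sd) feature matrix of env layers, cells in
# column-major cell order; the generating suitability model is log-linear in
# these features.
env_feature_matrix <- function(env, standardize = TRUE) {
  x <- vapply(env$layers, function(l) as.vector(l$values),
              numeric(env$grid$n_rows * env$grid$n_cols))
  if (standardize) x <- scale(x)
  colnames(x) <- names(env$layers)
  x
}

#' Simulate occurrence points with known suitability and sampling bias
#'
#' Cells are drawn with probability proportional to
#' `exp(beta_true . z(cell)) * bias(cell)`, where `z` are the landscape-
#' standardized environmental layers and the bias surface is a mixture of
#' quartic (biweight) kernels centred on `bias_centres` — an explicit stand-in
#' for the uneven collection effort presence-only records suffer from. Each
#' point is jittered uniformly within its cell.
#'
#' @param env an [env_stack()].
#' @param beta_true named numeric vector of generating coefficients (names
#'   must match env layer names; missing layers get 0).
#' @param bias_centres optional matrix/data.frame of (x, y) bias focus points;
#'   `NULL` means unbiased sampling.
#' @param n number of points to draw (>= 1).
#' @param seed integer RNG seed.
#' @param bias_bandwidth kernel bandwidth in metres (default 10 cells).
#' @param bias_floor minimum relative sampling weight in biased mode.
#' @return a [si_occurrences()] with `n` points.
#' @export
simulate_occurrences <- function(env, beta_true, bias_centres = NULL, n,
                                 seed = 1,
                                 bias_bandwidth = 10 * env$grid$cell_size,
                                 bias_floor = 0.05) {
  if (n < 1) stop("parameter error: n must be >= 1")
  grid <- env$grid
  z <- env_feature_matrix(env)
  beta <- stats::setNames(numeric(ncol(z)), colnames(z))
  beta[names(beta_true)] <- beta_true
  lp <- as.vector(z %*% beta)
  suit <- exp(lp - max(lp))
  bias <- rep(1, length(suit))
  if (!is.null(bias_centres)) {
    bc <- as.matrix(bias_centres)
    occ_b <- si_occurrences(bc[, 1], bc[, 2])
    bg <- build_bias_grid(occ_b, grid, bandwidth = bias_bandwidth,
                          floor_eps = bias_floor)
    bias <- as.vector(bg$layer$values)
  }
  wt <- suit * bias
  if (all(wt <= 0) || all(!is.finite(wt)))
    stop("degenerate-landscape error: all sampling weights are zero")
  with_seed(seed, {
    cells <- sample.int(length(wt), n, replace = TRUE, prob = wt)
    cc <- cell_centres(grid)
    row <- (cells - 1) %% grid$n_rows + 1
    col <- (cells - 1) %/% grid$n_rows + 1
    jx <- stats::runif(n, -0.5, 0.5) * grid$cell_size
    jy <- stats::runif(n, -0.5, 0.5) * grid$cell_size
    si_occurrences(cc$x[col] + jx, cc$y[row] + jy)
  })
}

#' Simulate zero-inflated plot-survey nest counts
#'
#' Each 10 x 10 m plot in class `c` is occupied with probability
#' `psi_true[c]`; an occupied plot holds `1 + Poisson(lambda_true[c] - 1)`
#' nests (so occupied plots always have at least one nest), an unoccupied
#' plot holds zero. The paper-style survey sees only these counts.
#'
#' @param class_params data.frame with columns `class`, `psi`, `lambda`
#'   (mean nests per *occupied* plot, >= 1).
#' @param n_plots named integer vector: class -> number of plots.
#' @param seed integer RNG seed.
#' @return data.frame with columns `class`, `plot_id`, `nests`.
#' @export
simulate_plot_surveys <- function(class_params, n_plots, seed = 1) {
  stopifnot(all(c("class", "psi", "lambda") %in% names(class_params)))
  if (any(class_params$psi < 0 | class_params$psi > 1))
    stop("parameter error: psi must be in [0, 1]")
  if (any(class_params$psi > 0 & class_params$lambda < 1))
    stop("parameter error: lambda must be >= 1 for occupied classes (an occupied plot has >= 1 nest)")
  if (any(n_plots < 1)) stop("parameter error: n_plots must be >= 1")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(class_params)), function(i) {
      cl <- class_params$class[i]
      np <- n_plots[[cl]]
      if (is.null(np)) stop("parameter error: no plot count for class ", cl)
      occupied <- stats::rbinom(np, 1, class_params$psi[i])
      nests <- occupied * (1 + stats::rpois(np, max(0, class_params$lambda[i] - 1)))
      data.frame(class = cl,
                 plot_id = sprintf("%s_%04d", cl, seq_len(np)),
                 nests = as.integer(nests), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a seasonal stack of hourly radiation layers
#'
#' Emulates the hourly sunshine-radiation data (MJ m-2 per hour) used to
#' count bright-sunshine foraging hours over a season. Each of
#' `season_days * hours_per_day` candidate daylight hours at a cell is
#' "bright" with a spatially smooth per-cell probability whose landscape
#' mean equals `mean_bright_fraction`; bright hours get radiation at or above
#' the bright-sunshine threshold, other hours get zero (night and overcast
#' collapse to zero radiation). The expected seasonal bright-hour count per
#' cell is therefore `mean_bright_fraction * season_days * hours_per_day`.
#'
#' @param grid a [si_grid()].
#' @param season_days days in the season (default 89: 1 Feb - 30 Apr,
#'   non-leap).
#' @param hours_per_day candidate daylight hours per day (default 12).
#' @param seed integer RNG seed.
#' @param mean_bright_fraction landscape-mean fraction of candidate hours
#'   that are bright, in [0, 1].
#' @param bright_threshold bright-sunshine radiation threshold in MJ m-2
#'   per hour (default 0.432, i.e. 120 W m-2).
#' @param spatial_sd spatial sd of the per-cell bright probability.
#' @return object of class `si_sunshine`: grid plus a
#'   `[n_rows, n_cols, n_hours]` radiation array and its threshold.
#' @export
generate_sunshine_stack <- function(grid, season_days = 89, hours_per_day = 12,
                                    seed = 1, mean_bright_fraction = 0.5,
                                    bright_threshold = 0.432,
                                    spatial_sd = 0.05) {
  if (mean_bright_fraction < 0 || mean_bright_fraction > 1)
    stop("parameter error: mean_bright_fraction must be in [0, 1]")
  nr <- grid$n_rows; nc <- grid$n_cols
  n_hours <- season_days * hours_per_day
  with_seed(seed, {
    p <- mean_bright_fraction + spatial_sd * gaussian_field(nr, nc, 6)
    p <- pmin(1, pmax(0, p))
    p <- pmin(1, pmax(0, p + (mean_bright_fraction - mean(p))))
    if (mean_bright_fraction == 0) p[] <- 0
    if (mean_bright_fraction == 1) p[] <- 1
    bright <- array(stats::runif(nr * nc * n_hours) < as.vector(p),
                    dim = c(nr, nc, n_hours))
    radiation <- array(0, dim = c(nr, nc, n_hours))
    nb <- sum(bright)
    if (nb > 0)
      radiation[bright] <- bright_threshold * (1 + stats::runif(nb, 0, 1.5))
    structure(list(grid = grid, radiation = radiation,
                   season_days = season_days, hours_per_day = hours_per_day,
                   bright_threshold = bright_threshold),
              class = "si_sunshine")
  })
}

#' Construct a sunshine stack from a radiation array
#'
#' @param radiation `[n_rows, n_cols, n_hours]` array of MJ m-2 per hour.
#' @param grid a [si_grid()].
#' @param bright_threshold bright-sunshine threshold (MJ m-2 per hour).
#' @return object of class `si_sunshine`.
#' @export
sunshine_stack <- function(radiation, grid, bright_threshold = 0.432) {
  stopifnot(length(dim(radiation)) == 3,
            dim(radiation)[1] == grid$n_rows, dim(radiation)[2] == grid$n_cols)
  structure(list(grid = grid, radiation = radiation,
                 season_days = NA_integer_,
                 hours_per_day = NA_integer_,
                 bright_threshold = bright_threshold),
            class = "si_sunshine")
}
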