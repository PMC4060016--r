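#' Grid geometry for aligned raster layers
#'
#' A `si_grid` describes the geometry every raster layer in a pipeline run
#' shares: number of rows and columns, square cell size in metres, projected
#' coordinates of the upper-left *corner*, and an opaque CRS label. Cells are
#' cell-centre registered; row 1 is the northernmost row.
#'
#' @param n_rows,n_cols integer grid dimensions (>= 1).
#' @param cell_size square cell edge in metres (default 500, i.e. 25 ha cells).
#' @param origin length-2 numeric, projected (x, y) of the upper-left corner.
#' @param crs_label opaque string naming the projection.
#' @return an object of class `si_grid`.
#' @examples
#' g <- si_grid(10, 10)
#' cell_area_ha(g)  # 25
#' @export
si_grid <- function(n_rows, n_cols, cell_size = 500,
                    origin = c(0, n_rows * cell_size),
                    crs_label = "local-metres") {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid dimensions must be >= 1")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  if (length(origin) != 2 || any(!is.finite(origin)))
    stop("origin must be two finite coordinates")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs_label = as.character(crs_label)),
    class = "si_grid")
}

#' @export
print.si_grid <- function(x, ...) {
  cat(sprintf("<si_grid> %d x %d cells, %.6g m resolution (%.6g ha/cell)\n",
              x$n_rows, x$n_cols, x$cell_size, cell_area_ha(x)))
  cat(sprintf("  upper-left corner (%.6g, %.6g), crs '%s'\n",
              x$origin[1], x$origin[2], x$crs_label))
  invisible(x)
}

#' Cell area in hectares
#'
#' @param grid a [si_grid()].
#' @return cell area in ha (`cell_size^2 / 1e4`); 25 for the default 500 m.
#' @export
cell_area_ha <- function(grid) grid$cell_size^2 / 1e4

#' Test whether two grids are identical (layers "aligned")
#'
#' All cross-layer raster operations require alignment: same dimensions,
#' resolution, origin and CRS label.
#'
#' @param a,b [si_grid()] objects.
#' @return logical.
#' @export
grids_aligned <- function(a, b) {
  isTRUE(a$n_rows == b$n_rows) && isTRUE(a$n_cols == b$n_cols) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin)) &&
    identical(a$crs_label, b$crs_label)
}

stop_if_misaligned <- function(a, b, what = "rasters") {
  if (!grids_aligned(grid_of(a), grid_of(b)))
    stop("alignment error: ", what, " are not on the same grid")
  invisible(TRUE)
}

grid_of <- function(x) if (inherits(x, "si_grid")) x else x$grid

#' A single georeferenced raster layer
#'
#' Values are stored as an `n_rows x n_cols` numeric matrix (row 1 = north).
#' Cells may be flagged nodata; nodata propagates through arithmetic and is
#' stored as NaN on disk.
#'
#' @param values numeric matrix of cell values.
#' @param grid the [si_grid()] the layer sits on.
#' @param nodata_mask logical matrix, `TRUE` where the cell is nodata
#'   (default: cells with non-finite values).
#' @param name,units descriptive strings carried through I/O.
#' @return an object of class `si_raster`.
#' @export
si_raster <- function(values, grid, nodata_mask = NULL,
                      name = "layer", units = "") {
  values <- as.matrix(values)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("values matrix does not match grid dimensions")
  if (is.null(nodata_mask)) nodata_mask <- !is.finite(values)
  nodata_mask <- matrix(as.logical(nodata_mask), grid$n_rows, grid$n_cols)
  if (any(!is.finite(values[!nodata_mask])))
    stop("non-finite values outside the nodata mask")
  values[nodata_mask] <- NaN
  structure(list(grid = grid, values = values, nodata_mask = nodata_mask,
                 name = as.character(name), units = as.character(units)),
            class = "si_raster")
}

#' @export
print.si_raster <- function(x, ...) {
  v <- x$values[!x$nodata_mask]
  cat(sprintf("<si_raster> '%s'%s, %d x %d, %d nodata cell(s)\n",
              x$name, if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              x$grid$n_rows, x$grid$n_cols, sum(x$nodata_mask)))
  if (length(v))
    cat(sprintf("  range %.6g .. %.6g, mean %.6g\n",
                min(v), max(v), mean(v)))
  invisible(x)
}

#' Coordinates of cell centres
#'
#' @param grid a [si_grid()].
#' @return list with `x` (length `n_cols`) and `y` (length `n_rows`) centre
#'   coordinates; `y` decreases with row index (row 1 = north).
#' @export
cell_centres <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$n_cols) - 0.5) * grid$cell_size,
       y = grid$origin[2] - (seq_len(grid$n_rows) - 0.5) * grid$cell_size)
}

#' Map projected points to cell row/column indices
#'
#' @param grid a [si_grid()].
#' @param x,y projected coordinates.
#' @return data.frame with `row`, `col` (NA when outside the grid extent).
#' @export
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1
  row <- floor((grid$origin[2] - y) / grid$cell_size) + 1
  # points exactly on the east/south edge belong to the last cell
  col[x == grid$origin[1] + grid$n_cols * grid$cell_size] <- grid$n_cols
  row[y == grid$origin[2] - grid$n_rows * grid$cell_size] <- grid$n_rows
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows |
    !is.finite(x) | !is.finite(y)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' A set of occurrence points in projected coordinates
#'
#' @param x,y numeric coordinate vectors (no NA).
#' @param source_labels optional character vector of provenance labels.
#' @return object of class `si_occurrences` with a `points` matrix.
#' @export
si_occurrences <- function(x, y, source_labels = NULL) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("occurrence coordinates must be finite")
  structure(list(points = cbind(x = as.numeric(x), y = as.numeric(y)),
                 source_labels = source_labels),
            class = "si_occurrences")
}

#' @export
print.si_occurrences <- function(x, ...) {
  cat(sprintf("<si_occurrences> %d point(s)\n", nrow(x$points)))
  invisible(x)
}

#' @export
length.si_occurrences <- function(x) nrow(x$points)
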