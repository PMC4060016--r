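# Tabular I/O: occurrence CSVs and plot-survey tables.
# Dialect: UTF-8, comma-separated, header row required.

#' Read occurrence points from CSV, filtered to a grid extent
#'
#' Expects columns `x,y` in the grid's projected coordinates. Rows with
#' malformed coordinates or falling outside the grid extent are dropped and
#' the counts logged, so ingest filtering is auditable.
#'
#' @param path CSV file with columns `x`, `y` (extra columns ignored; an
#'   optional `source` column is kept as labels).
#' @param grid the [si_grid()] defining the extent.
#' @return a [si_occurrences()] object.
#' @export
read_occurrences <- function(path, grid) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop("format error: occurrence CSV must have columns x,y")
  n_in <- nrow(df)
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  ok <- is.finite(x) & is.finite(y)
  idx <- cell_index(grid, ifelse(ok, x, NA), ifelse(ok, y, NA))
  keep <- ok & !is.na(idx$row)
  log_info("read_occurrences: %d rows in, %d kept, %d dropped (malformed or outside extent)",
           n_in, sum(keep), n_in - sum(keep))
  if (!any(keep)) stop("empty-input error: no valid occurrence points inside the grid extent")
  labels <- if ("source" %in% names(df)) df$source[keep] else NULL
  si_occurrences(x[keep], y[keep], source_labels = labels)
}

#' Write occurrence points to CSV
#'
#' @param occ a [si_occurrences()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  df <- as.data.frame(occ$points)
  if (!is.null(occ$source_labels)) df$source <- occ$source_labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a plot-survey table from CSV
#'
#' Plots are fixed 10 x 10 m (0.01 ha). Validates the `class,plot_id,nests`
#' schema: nest counts must be non-negative integers and plot ids unique
#' within a land-cover class.
#'
#' @param path CSV with columns `class`, `plot_id`, `nests`.
#' @return a validated `data.frame`.
#' @export
read_plot_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_plot_table(df)
}

validate_plot_table <- function(df) {
  if (!all(c("class", "plot_id", "nests") %in% names(df)))
    stop("format error: plot table must have columns class,plot_id,nests")
  if (nrow(df) == 0) stop("empty-input error: plot table has no rows")
  nests <- suppressWarnings(as.numeric(df$nests))
  if (any(!is.finite(nests)) || any(nests < 0) || any(nests != round(nests)))
    stop("validation error: nest counts must be non-negative integers")
  dup <- stats::aggregate(plot_id ~ class, df, function(p) anyDuplicated(p) > 0)
  if (any(dup$plot_id))
    stop("validation error: duplicate plot_id within class ",
         paste(dup$class[dup$plot_id], collapse = ", "))
  df$nests <- as.integer(nests)
  df
}
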