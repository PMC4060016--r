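# Shared fixtures: everything is built in code at test time.

options(stepimpact.quiet = TRUE)

# A small environment stack, memoised per (size, seed) within a test run.
tiny_env <- local({
  cache <- list()
  function(n = 40, seed = 11, smoothness = 6) {
    key <- paste(n, seed, smoothness)
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_env_stack(si_grid(n, n), seed = seed,
                                          smoothness = smoothness)
    cache[[key]]
  }
})

# Column-major cell indices of occurrence points on a grid.
occ_cells <- function(occ, grid) {
  idx <- cell_index(grid, occ$points[, 1], occ$points[, 2])
  (idx$col - 1L) * grid$n_rows + idx$row
}

# Landscape-standardized linear predictor of a generating coefficient vector.
true_linear_predictor <- function(env, beta_true) {
  z <- vapply(env$layers, function(l) as.vector(scale(as.vector(l$values))),
              numeric(env$grid$n_rows * env$grid$n_cols))
  bt <- stats::setNames(numeric(ncol(z)), colnames(z))
  bt[names(beta_true)] <- beta_true
  as.vector(z %*% bt)
}

# A plot table with a given number of plots and total nests for one class
# (nests spread one per plot, so occupancy = n_nests / n_plots unless stated).
make_plots <- function(class, n_plots, n_nests, n_occupied = n_nests) {
  stopifnot(n_occupied <= n_plots, n_nests >= n_occupied)
  nests <- integer(n_plots)
  if (n_occupied > 0) {
    nests[seq_len(n_occupied)] <- 1L
    extra <- n_nests - n_occupied
    if (extra > 0)  # pile remaining nests on the first plots
      nests[seq_len(extra) %% n_occupied + 1] <-
        nests[seq_len(extra) %% n_occupied + 1] + 1L
  }
  data.frame(class = class,
             plot_id = sprintf("%s_%04d", class, seq_len(n_plots)),
             nests = nests, stringsAsFactors = FALSE)
}
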