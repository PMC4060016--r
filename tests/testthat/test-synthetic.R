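# Synthetic landscape generators: determinism, construction invariants, and
# recovery of the generating parameters at large n.

test_that("generators are pure functions of (parameters, seed)", {
  g <- si_grid(20, 20)
  e1 <- generate_env_stack(g, seed = 1)
  e2 <- generate_env_stack(g, seed = 1)
  expect_identical(e1$layers$elevation$values, e2$layers$elevation$values)
  expect_identical(e1$layers$degree_days$values, e2$layers$degree_days$values)

  w <- c(HSV = 0.3, SAS = 0.7)
  expect_identical(generate_landcover(g, w, seed = 9)$values,
                   generate_landcover(g, w, seed = 9)$values)

  params <- data.frame(class = "HSV", psi = 0.5, lambda = 1.3)
  expect_identical(simulate_plot_surveys(params, c(HSV = 50), seed = 2),
                   simulate_plot_surveys(params, c(HSV = 50), seed = 2))

  env <- tiny_env(20, seed = 1)
  o1 <- simulate_occurrences(env, c(elevation = 1), n = 30, seed = 5)
  o2 <- simulate_occurrences(env, c(elevation = 1), n = 30, seed = 5)
  expect_identical(o1$points, o2$points)

  s1 <- generate_sunshine_stack(g, seed = 3, mean_bright_fraction = 0.4)
  s2 <- generate_sunshine_stack(g, seed = 3, mean_bright_fraction = 0.4)
  expect_identical(s1$radiation, s2$radiation)
})

test_that("environmental stack satisfies its construction invariants", {
  env <- tiny_env(40, seed = 11)
  expect_true(all(env$layers$degree_days$values >= 0))
  expect_true(all(env$layers$tmax$values >= env$layers$tmin$values))
  for (l in env$layers) expect_true(grids_aligned(l$grid, env$grid))
  expect_error(generate_env_stack(si_grid(10, 10), smoothness = 0.5),
               "smoothness")
})

test_that("smoothed fields are spatially autocorrelated (Moran's I oracle)", {
  env <- generate_env_stack(si_grid(50, 50), seed = 7, smoothness = 8)
  v <- env$layers$elevation$values
  # lag-1 rook-neighbour Moran's I by direct summation
  z <- v - mean(v)
  num <- sum(z[-nrow(z), ] * z[-1, ]) + sum(z[, -ncol(z)] * z[, -1])
  w_n <- (nrow(z) - 1) * ncol(z) + nrow(z) * (ncol(z) - 1)
  moran <- (length(z) / w_n) * (num / sum(z^2))
  expect_gt(moran, 0.5)
})

test_that("degree days accumulate positive excess over the base", {
  expect_equal(compute_degree_days(rep(10, 365)), 0)
  expect_equal(compute_degree_days(rep(11, 365)), 365)
  temps <- 12 + 8 * sin(2 * pi * seq_len(365) / 365)
  oracle <- 0
  for (d in seq_len(365)) oracle <- oracle + max(0, temps[d] - 10)
  expect_equal(compute_degree_days(temps), oracle)
  expect_error(compute_degree_days(c(rep(10, 364), NA)), "non-finite")
  expect_error(compute_degree_days(rep(10, 12)), "365")
})

test_that("land cover hits requested class frequencies and stays patchy", {
  g <- si_grid(200, 200)
  w <- c(HSV = 0.1, BUA = 0.2, SAS = 0.7)
  lc <- generate_landcover(g, w, seed = 4, patchiness = 5)
  codes <- landcover_codes(lc)
  freq <- table(codes) / length(codes)
  expect_true(all(abs(freq[names(w)] - w) < 0.03))
  # degenerate single class
  lc1 <- generate_landcover(si_grid(15, 15), c(FOR = 1), seed = 1)
  expect_true(all(landcover_codes(lc1) == "FOR"))
  expect_error(generate_landcover(g, c(XYZ = 1)), "schema error")
  expect_error(generate_landcover(g, c(HSV = 0.5, BUA = 0.4)), "sum to 1")
})

test_that("unbiased flat-suitability occurrences are spatially uniform", {
  env <- tiny_env(40, seed = 11)
  g <- env$grid
  set.seed(77)
  pvals <- replicate(50, {
    occ <- simulate_occurrences(env, c(elevation = 0), n = 200,
                                seed = sample.int(1e6, 1))
    idx <- cell_index(g, occ$points[, 1], occ$points[, 2])
    quad <- factor(2 * (idx$row > g$n_rows / 2) + (idx$col > g$n_cols / 2),
                   levels = 0:3)
    suppressWarnings(chisq.test(table(quad)))$p.value
  })
  # at alpha = 0.01 under the null, 50 runs should essentially never reject
  expect_lte(sum(pvals < 0.01), 3)
})

test_that("occurrences track the generating suitability and count", {
  env <- tiny_env(40, seed = 11)
  occ <- simulate_occurrences(env, c(solar_radiation = 2), n = 253, seed = 9)
  expect_equal(length(occ), 253L)
  cells <- occ_cells(occ, env$grid)
  expect_gt(mean(env$layers$solar_radiation$values[cells]),
            mean(env$layers$solar_radiation$values))
})

test_that("plot surveys are zero-inflated shifted-Poisson with given psi", {
  params0 <- data.frame(class = "FOR", psi = 0, lambda = 1)
  t0 <- simulate_plot_surveys(params0, c(FOR = 40), seed = 1)
  expect_true(all(t0$nests == 0))

  params <- data.frame(class = "HSV", psi = 0.27, lambda = 1.25)
  tb <- simulate_plot_surveys(params, c(HSV = 10000), seed = 2)
  expect_lt(abs(mean(tb$nests >= 1) - 0.27), 0.02)
  occupied <- tb$nests[tb$nests >= 1]
  expect_true(all(occupied >= 1))
  expect_lt(abs(mean(occupied) - 1.25), 0.05)

  bad <- data.frame(class = "HSV", psi = 0.5, lambda = 0.5)
  expect_error(simulate_plot_surveys(bad, c(HSV = 10)), "lambda")
})

test_that("sunshine stack hits the target seasonal bright-hour budget", {
  g <- si_grid(50, 50)
  s0 <- generate_sunshine_stack(g, seed = 1, mean_bright_fraction = 0)
  expect_true(all(s0$radiation == 0))

  target <- 540
  s <- generate_sunshine_stack(g, seed = 2,
                               mean_bright_fraction = target / (89 * 12))
  hours <- seasonal_foraging_hours(s)
  expect_lt(abs(mean(hours$layer$values) - target), 15)
  expect_true(all(hours$layer$values <= 89 * 12))
  expect_error(generate_sunshine_stack(g, mean_bright_fraction = 1.2),
               "mean_bright_fraction")
})
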