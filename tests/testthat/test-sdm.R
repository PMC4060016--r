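# Bias grid, background sampling, features, the penalized log-linear fit,
# AUC and thresholding.

test_that("bias grid equals brute-force quartic kernel summation", {
  g <- si_grid(9, 9, cell_size = 500, origin = c(0, 4500))
  occ <- si_occurrences(c(1100, 3300), c(1200, 3600))
  h <- 1500
  bg <- build_bias_grid(occ, g, bandwidth = h, floor_eps = 1e-6)
  cc <- cell_centres(g)
  oracle <- matrix(0, 9, 9)
  for (r in 1:9) for (c in 1:9) {
    for (p in 1:2) {
      d <- sqrt((cc$x[c] - occ$points[p, 1])^2 + (cc$y[r] - occ$points[p, 2])^2)
      if (d <= h) oracle[r, c] <- oracle[r, c] +
          (3 / (pi * h^2)) * (1 - (d / h)^2)^2
    }
  }
  oracle <- pmax(oracle / max(oracle), 1e-6)
  expect_lt(max(abs(bg$layer$values - oracle)), 1e-12)
})

test_that("bias grid: kernel mode, compact support floor, symmetry", {
  g <- si_grid(11, 11, cell_size = 500, origin = c(0, 5500))
  cc <- cell_centres(g)
  occ1 <- si_occurrences(cc$x[6], cc$y[6])
  bg <- build_bias_grid(occ1, g, bandwidth = 900)
  expect_equal(bg$layer$values[6, 6], 1)
  expect_equal(max(bg$layer$values), 1)
  expect_equal(bg$layer$values[1, 1], bg$floor_eps)  # beyond support
  # symmetric points about the centre give a symmetric surface
  occ2 <- si_occurrences(c(cc$x[3], cc$x[9]), c(cc$y[6], cc$y[6]))
  bg2 <- build_bias_grid(occ2, g, bandwidth = 1200)
  expect_equal(bg2$layer$values, bg2$layer$values[, 11:1])
  expect_error(build_bias_grid(occ1, g, bandwidth = 0), "bandwidth")
})

test_that("background sampling follows the bias surface", {
  g <- si_grid(20, 20)
  # uniform bias: quadrant occupancy passes a chi-square uniformity check
  set.seed(42)
  pvals <- replicate(50, {
    cells <- sample_background(g, uniform_bias_grid(g), 200,
                               seed = sample.int(1e6, 1))
    row <- (cells - 1) %% 20 + 1; col <- (cells - 1) %/% 20 + 1
    quad <- factor(2 * (row > 10) + (col > 10), levels = 0:3)
    suppressWarnings(chisq.test(table(quad)))$p.value
  })
  expect_lte(sum(pvals < 0.01), 3)

  # extreme contrast: nearly all samples land in the heavy region
  w <- matrix(1e-6, 20, 20); w[1:5, 1:5] <- 1
  bias <- structure(list(layer = si_raster(w, g), bandwidth = NA,
                         floor_eps = 1e-6), class = "si_biasgrid")
  cells <- sample_background(g, bias, 20, seed = 1)
  row <- (cells - 1) %% 20 + 1; col <- (cells - 1) %/% 20 + 1
  expect_gte(mean(row <= 5 & col <= 5), 0.95)

  expect_identical(sample_background(g, uniform_bias_grid(g), 50, seed = 9),
                   sample_background(g, uniform_bias_grid(g), 50, seed = 9))
  expect_error(sample_background(g, uniform_bias_grid(g), 401), "exceeds")
})

test_that("feature building standardizes on background and drops constants", {
  env <- tiny_env(20, seed = 1)
  g <- env$grid
  bg <- seq_len(20 * 20)
  st <- feature_standardization(env, bg)
  spec_lin <- feature_spec(names(env$layers), quadratic = FALSE)
  x <- build_features(env, bg, spec_lin, st)
  expect_equal(ncol(x), 6)
  expect_equal(unname(colMeans(x)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(x, 2, sd)), rep(1, 6), tolerance = 1e-12)

  spec_q <- feature_spec(names(env$layers))
  xq <- build_features(env, bg, spec_q, st)
  expect_equal(xq[, "elevation^2"], xq[, "elevation"]^2)

  # a constant layer is dropped with one logged warning
  env2 <- env_stack(c(env$layers,
                      list(flat = si_raster(matrix(3, 20, 20), g))))
  st2 <- feature_standardization(env2, bg)
  expect_false("flat" %in% st2$variables)
  x2 <- build_features(env2, bg, feature_spec(names(env2$layers),
                                              quadratic = FALSE), st2)
  expect_equal(ncol(x2), 6)
})

test_that("heavy regularization collapses to the null model", {
  set.seed(5)
  xb <- matrix(rnorm(400), 200, 2)
  xp <- xb[sample.int(200, 50, replace = TRUE), ]  # presences = background
  fit <- fit_maxent(xp, xb, reg_lambda = 100)
  expect_equal(unname(fit$beta), c(0, 0))
  expect_equal(unname(predict(fit, xb)), rep(0.5, 200))
  # raw output is a probability distribution over the background sample
  expect_equal(sum(predict(fit, xb, type = "raw")), 1)
})

test_that("1-D fit matches an independent optimizer of the same objective", {
  set.seed(8)
  xb <- matrix(seq(-2, 2, length.out = 200), ncol = 1)
  xp <- matrix(rep(c(1.2, 1.5, 1.8, 2.0), 5), ncol = 1)
  lam <- 0.05
  fit <- fit_maxent(xp, xb, reg_lambda = lam)
  obj <- function(b) -(mean(xp * b) - log(sum(exp(xb * b))) - lam * abs(b))
  oracle <- stats::optimize(obj, c(-10, 10), tol = 1e-10)$minimum
  expect_gt(fit$beta[1], 0)
  expect_lt(abs(fit$beta[1] - oracle), 1e-3)
})

test_that("fitted suitability recovers the generating suitability ranking", {
  env <- generate_env_stack(si_grid(100, 100), seed = 11)
  beta_true <- c(degree_days = 1.2, elevation = -0.6,
                 solar_radiation = 0.6, rainfall = -0.4)
  occ <- simulate_occurrences(env, beta_true, n = 2000, seed = 21)
  bg <- seq_len(100 * 100)
  spec <- feature_spec(names(env$layers), quadratic = FALSE)
  st <- feature_standardization(env, bg)
  fit <- fit_maxent(build_features(env, occ_cells(occ, env$grid), spec, st),
                    build_features(env, bg, spec, st))
  lp_fit <- as.vector(build_features(env, bg, spec, st) %*% fit$beta)
  expect_gt(cor(lp_fit, true_linear_predictor(env, beta_true),
                method = "spearman"), 0.95)
})

test_that("AUC matches exhaustive pair counting and its edge cases", {
  expect_equal(compute_auc(c(2, 3), c(0, 1)), 1)
  expect_equal(compute_auc(rep(1, 5), rep(1, 7)), 0.5)
  expect_equal(compute_auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  set.seed(10)
  for (rep in 1:5) {
    sp <- sample(seq(0, 1, 0.05), sample(5:200, 1), replace = TRUE)
    sb <- sample(seq(0, 1, 0.05), sample(5:200, 1), replace = TRUE)
    pairs <- outer(sp, sb, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(compute_auc(sp, sb), mean(pairs))
    # invariance under a strictly monotone transform
    expect_equal(compute_auc(exp(3 * sp), exp(3 * sb)), mean(pairs))
  }
  expect_error(compute_auc(numeric(0), 1), "empty")
})

test_that("minimum-training-presence threshold uses the nearest rank", {
  expect_equal(mtp_threshold(rep(0.3, 8)), 0.3)
  expect_equal(mtp_threshold(0.42), 0.42)
  expect_equal(mtp_threshold(seq(0.1, 1, 0.1)), 0.1)   # ceil(1) = 1st smallest
  expect_equal(mtp_threshold(seq(0.1, 1, 0.1), percentile = 25), 0.3)
  expect_error(mtp_threshold(numeric(0)), "input error")
})
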