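# Foraging success rate, seasonal foraging hours, and the impact surface.

test_that("foraging success rate multiplies its components", {
  expect_equal(foraging_success_rate(0.33, 0.30, 0.75), 4.455)
  expect_equal(round_half_up(foraging_success_rate(0.33, 0.30, 0.75), 1), 4.5)
  expect_equal(foraging_success_rate(0.23, 0.25, 0.70), 2.415)
  expect_equal(foraging_success_rate(0.46, 0.38, 0.80), 8.3904)
  expect_equal(foraging_success_rate(0, 0.3, 0.5), 0)
  expect_equal(foraging_success_rate(0.33, 0, 0.5), 0)
  expect_error(foraging_success_rate(0.3, 1.2, 0.5), "proportions")
  expect_error(foraging_success_rate(-0.1, 0.3, 0.5), "non-negative")
})

test_that("component means exclude flagged outliers", {
  cm <- component_means(c(0.70, 0.80, 0.75, 0.12), exclusions = 0.12)
  expect_equal(cm$mean, 0.75)
  expect_equal(cm$range, c(0.70, 0.80))
  single <- component_means(0.33)
  expect_equal(single$mean, 0.33)
  expect_equal(single$range, c(0.33, 0.33))
  expect_equal(component_means(c(0.2, 0.4))$mean, 0.3)
  expect_error(component_means(c(0.1), exclusions = 0.1), "all values")
})

test_that("seasonal hours count threshold exceedances (closed bound)", {
  g <- si_grid(3, 3)
  zero <- sunshine_stack(array(0, c(3, 3, 600)), g)
  expect_true(all(seasonal_foraging_hours(zero)$layer$values == 0))

  # a cell with exactly 519 bright hours counts exactly 519
  rad <- array(0, c(3, 3, 1068))
  rad[2, 2, seq_len(519)] <- 0.432          # exactly at the threshold
  rad[1, 1, seq_len(100)] <- 0.431999       # just below: not counted
  s <- sunshine_stack(rad, g, bright_threshold = 0.432)
  h <- seasonal_foraging_hours(s)
  expect_equal(h$layer$values[2, 2], 519)
  expect_equal(h$layer$values[1, 1], 0)
})

test_that("impact arithmetic: nests x success x hours, masked", {
  g <- si_grid(2, 2)
  ct <- default_class_table()
  lc <- si_raster(matrix(match(c("HSV", "HSV", "WAT", "SAS"), ct$code), 2, 2), g)
  mask <- si_raster(matrix(c(1, 0, 1, 1), 2, 2), g)
  est <- data.frame(class = c("HSV", "SAS"), occupancy = c(0.27, 0.09),
                    density = c(34, 9), stringsAsFactors = FALSE)
  hours <- structure(list(layer = si_raster(matrix(500, 2, 2), g),
                          bright_threshold = 0.432), class = "si_hours")
  imp <- impact_surface(mask, lc, est, 4.455, hours)
  # suitable HSV cell: nests = 25 * 0.27 * 34 = 229.5; prey = 229.5*4.455*500
  expect_equal(imp$nests$values[1, 1], 229.5)
  expect_equal(imp$layer$values[1, 1], 511211.25)
  expect_equal(imp$layer$values[2, 1], 0)          # outside mask
  expect_equal(imp$layer$values[1, 2], 0)          # unsuitable class
  expect_equal(imp$layer$values[2, 2], 25 * 0.09 * 9 * 4.455 * 500)
})

test_that("uniform hours make raster and table routes agree exactly", {
  g <- si_grid(10, 10)
  ct <- default_class_table()
  set.seed(12)
  codes <- matrix(sample(c("HSV", "BUA", "SAS", "FOR"), 100, replace = TRUE),
                  10, 10)
  lc <- si_raster(matrix(match(codes, ct$code), 10, 10), g)
  mask <- si_raster(matrix(rbinom(100, 1, 0.5), 10, 10), g)
  est <- data.frame(class = c("HSV", "BUA", "SAS", "FOR"),
                    occupancy = c(0.27, 0.23, 0.09, 0),
                    density = c(34, 29, 9, 0), stringsAsFactors = FALSE)
  H <- 540
  hours <- structure(list(layer = si_raster(matrix(H, 10, 10), g),
                          bright_threshold = 0.432), class = "si_hours")
  f_rate <- foraging_success_rate()
  imp <- impact_surface(mask, lc, est, f_rate, hours)
  # distributivity: sum(nests_i * F * H) == (sum nests_i) * F * H
  expect_equal(sum(imp$layer$values), sum(imp$nests$values) * f_rate * H)
  # and the unfloored table total equals the cellwise total
  est2 <- cbind(est, n_plots = 0L, n_nests = 0L,
                provenance = c(rep("surveyed", 4)))
  tab <- extrapolate(class_area(lc, mask), est2)
  expect_equal(extrapolation_totals(tab)$total_nests_raw,
               sum(imp$nests$values))
})

test_that("impact is monotone in success rate and national totals scale", {
  g <- si_grid(4, 4)
  ct <- default_class_table()
  lc <- si_raster(matrix(match("HSV", ct$code), 4, 4), g)
  mask <- si_raster(matrix(1, 4, 4), g)
  est <- data.frame(class = "HSV", occupancy = 0.27, density = 34)
  hours <- structure(list(layer = si_raster(matrix(500, 4, 4), g),
                          bright_threshold = 0.432), class = "si_hours")
  i1 <- impact_surface(mask, lc, est, 4.455, hours)
  i2 <- impact_surface(mask, lc, est, 4.455 / 2, hours)
  expect_equal(sum(i2$layer$values), sum(i1$layer$values) / 2)

  tot0 <- national_totals(table = NULL, success_rate = 4.5, mean_hours = 540)
  expect_true(is.na(tot0$table_total_prey))
  tab <- extrapolate(c(HSV = 0), est = cbind(est, n_plots = 0L, n_nests = 0L,
                                             provenance = "surveyed"))
  tz <- national_totals(table = tab, success_rate = 4.5, mean_hours = 540)
  expect_equal(tz$table_total_prey, 0)
})

test_that("reference sunshine table yields the ~540 h seasonal mean", {
  ref <- reference_sunshine_hours()
  inside <- ref$season_hours[ref$within_distribution %in% TRUE]
  expect_length(inside, 7)
  expect_equal(mean(inside), mean(c(519, 529, 576, 550, 526, 553, 528)))
  expect_lt(abs(mean(inside) - 540), 1)
})
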