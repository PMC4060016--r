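# Grid geometry, raster round-trips and occurrence ingest.

test_that("grid geometry: 500 m cells are 25 ha and invariants are enforced", {
  g <- si_grid(10, 8)
  expect_equal(cell_area_ha(g), 25)
  expect_equal(cell_area_ha(si_grid(3, 3, cell_size = 100)), 1)
  expect_error(si_grid(0, 5), "dimensions")
  expect_error(si_grid(5, 5, cell_size = -1), "cell_size")
})

test_that("cell_index maps centres and edges to the right cells", {
  g <- si_grid(4, 4, cell_size = 500, origin = c(0, 2000))
  cc <- cell_centres(g)
  idx <- cell_index(g, cc$x[2], cc$y[3])
  expect_equal(idx$row, 3L)
  expect_equal(idx$col, 2L)
  expect_true(is.na(cell_index(g, -10, 1000)$row))   # outside west
  expect_equal(cell_index(g, 2000, 0)$row, 4L)       # far corner belongs in
})

test_that("write/read round-trips values, geometry and nodata mask", {
  set.seed(3)
  g <- si_grid(6, 9, cell_size = 500, origin = c(1e5, 2e5),
               crs_label = "local-metres")
  v <- matrix(rnorm(54) * 1000, 6, 9)
  v[c(5, 17, 40)] <- NA  # 3 nodata cells
  r <- si_raster(v, g, name = "elev", units = "m")
  p <- withr::local_tempfile(fileext = ".tif")
  write_raster(r, p)
  r2 <- read_raster(p)
  expect_true(grids_aligned(r2$grid, g))
  expect_identical(r2$nodata_mask, r$nodata_mask)
  expect_equal(r2$name, "elev")
  expect_equal(r2$units, "m")
  # values agree at float32 precision, and a second round-trip is bit-exact
  expect_equal(r2$values, r$values, tolerance = 1e-6)
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_raster(r2, p2)
  r3 <- read_raster(p2)
  expect_identical(r3$values, r2$values)
  expect_identical(r3$nodata_mask, r2$nodata_mask)
})

test_that("constant layer round-trips exactly and keeps 25 ha cells", {
  g <- si_grid(4, 4)
  r <- si_raster(matrix(7, 4, 4), g, name = "const")
  p <- withr::local_tempfile(fileext = ".tif")
  write_raster(r, p)
  r2 <- read_raster(p)
  expect_identical(r2$values, r$values)   # 7 is exact in float32
  expect_equal(cell_area_ha(r2$grid), 25)
})

test_that("our GeoTIFFs agree with an independent TIFF reader", {
  set.seed(4)
  g <- si_grid(5, 7, cell_size = 500, origin = c(1000, 9000))
  v <- matrix(rnorm(35), 5, 7); v[8] <- NA
  r <- si_raster(v, g, name = "x")
  p <- withr::local_tempfile(fileext = ".tif")
  write_raster(r, p)
  csvp <- withr::local_tempfile(fileext = ".csv")
  script <- sprintf(paste0(
    "import tifffile, numpy as np\n",
    "a = tifffile.imread(%s).astype('float64')\n",
    "np.savetxt(%s, a, delimiter=',')\n"),
    deparse(p), deparse(csvp))
  system2("python", "-", input = script, stdout = TRUE, stderr = TRUE)
  ext <- as.matrix(utils::read.csv(csvp, header = FALSE))
  dimnames(ext) <- NULL
  expect_equal(ext[!r$nodata_mask], r$values[!r$nodata_mask], tolerance = 1e-6)
  expect_true(all(is.nan(ext[r$nodata_mask])))
})

test_that("multi-band and misaligned writes are rejected", {
  p <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, c(4, 4, 3)), p, compression = "none")
  expect_error(read_raster(p), "multi-band")
  r <- si_raster(matrix(1, 3, 3), si_grid(3, 3))
  expect_error(write_raster(r, p, expect_grid = si_grid(4, 4)), "alignment")
})

test_that("occurrence ingest filters to extent and logs drops", {
  g <- si_grid(4, 4, cell_size = 500, origin = c(0, 2000))
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = c(250, 750, 1900), y = c(250, 1900, 1000)), p,
            row.names = FALSE)
  occ <- read_occurrences(p, g)
  expect_equal(length(occ), 3L)

  write.csv(data.frame(x = c(250, 99999), y = c(250, 250)), p, row.names = FALSE)
  withr::local_options(stepimpact.quiet = FALSE)
  expect_message(occ <- read_occurrences(p, g), "1 dropped")
  expect_equal(length(occ), 1L)

  write.csv(data.frame(x = numeric(), y = numeric()), p, row.names = FALSE)
  expect_error(suppressMessages(read_occurrences(p, g)), "empty-input")
  write.csv(data.frame(lonely = 1), p, row.names = FALSE)
  expect_error(read_occurrences(p, g), "format error")
})

test_that("plot table validation catches schema and value errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(class = "HSV", plot_id = c("a", "a"), nests = c(1, 0)),
            p, row.names = FALSE)
  expect_error(read_plot_table(p), "duplicate plot_id")
  write.csv(data.frame(class = "HSV", plot_id = "a", nests = -1), p,
            row.names = FALSE)
  expect_error(read_plot_table(p), "non-negative")
  write.csv(data.frame(class = "HSV", plot_id = "a", nests = 2), p,
            row.names = FALSE)
  expect_equal(read_plot_table(p)$nests, 2L)
})
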