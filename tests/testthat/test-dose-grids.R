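test_that("dose_grid enforces its invariants", {
  expect_s3_class(dose_grid(c(0, 1, 2), spacing = 1), "dose_grid")
  expect_error(dose_grid(c(1, -0.1), spacing = 1), "non-negative")
  expect_error(dose_grid(c(1, NA), spacing = 1), "finite")
  expect_error(dose_grid(1, spacing = 1), "at least 2 nodes")
  expect_error(dose_grid(c(1, 2), spacing = 0), "positive")
  expect_error(dose_grid(array(1, c(2, 2, 2, 2)), spacing = rep(1, 4)), "1 to 3")
})

test_that("node coordinates follow origin + i * spacing", {
  g <- dose_grid(matrix(0:5, 2, 3), spacing = c(2, 1.5), origin = c(-1, 10))
  expect_equal(grid_axis_coords(g, 1), c(-1, 1))
  expect_equal(grid_axis_coords(g, 2), c(10, 11.5, 13))
  expect_equal(grid_extent(g), rbind(lo = c(-1, 10), hi = c(1, 13)))
})

test_that("resample_to is exact at nodes and linear between them", {
  g <- dose_grid(c(0, 2), spacing = 1)
  expect_equal(resample_to(g, 0.25), 0.5)
  expect_equal(resample_to(g, c(0, 1)), c(0, 2))
  # monotone between neighbouring nodes in 1D
  xs <- seq(0, 1, by = 0.05)
  expect_false(is.unsorted(resample_to(g, xs)))
  expect_error(resample_to(g, 1.5), "outside")
  expect_true(is.na(resample_to(g, 1.5, outside = "na")))
})

test_that("multilinear functions are reproduced exactly", {
  set.seed(7)
  co <- runif(4, -2, 2)
  f <- function(p) 10 + co[1] * p[, 1] + co[2] * p[, 2] + co[3] * p[, 3]
  g <- dose_grid(array(0, c(4, 5, 6)), spacing = c(2, 1, 3), origin = c(-1, 0, 2))
  g$values[] <- f(grid_node_coords(g))
  q <- cbind(runif(50, -1, 5), runif(50, 0, 4), runif(50, 2, 17))
  expect_equal(resample_to(g, q), f(q), tolerance = 1e-12)
})

test_that("scan CSV writes and re-reads curves faithfully", {
  ddc <- gen_ddc(beam_model_spec(23.0), depths = seq(0, 300, by = 1))
  ocr <- gen_ocr(beam_model_spec(23.0), depth_mm = 15)
  path <- tempfile(fileext = ".csv")
  write_scan_csv(list(ddc, ocr), path)
  curves <- read_scan_csv(path)
  expect_length(curves, 2)
  expect_identical(curves[[1]]$curve_kind, "DDC")
  expect_identical(curves[[2]]$curve_kind, "OCR")
  expect_equal(curves[[2]]$depth_mm, 15)
  expect_equal(curves[[2]]$collimator, "mlc")
  expect_equal(as.vector(curves[[1]]$values), as.vector(ddc$values),
               tolerance = 1e-6)
  expect_equal(grid_axis_coords(curves[[1]], 1), grid_axis_coords(ddc, 1))
})

test_that("malformed scan CSV input is rejected with a line number", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("# kind: DDC", "# collimator: fixed", "# field_size_mm: 10",
               "0,1.0", "2,1.1", "1,1.2"), path)
  expect_error(read_scan_csv(path), "line 6.*increasing")
  writeLines(c("# kind: DDC", "# collimator: fixed", "0,1.0", "1,1.1"), path)
  expect_error(read_scan_csv(path), "field_size_mm")
  writeLines(c("# kind: DDC", "# collimator: fixed", "# field_size_mm: 10",
               "0,1.0", "1,abc"), path)
  expect_error(read_scan_csv(path), "line 5")
})

test_that("portable grid round trip is lossless", {
  set.seed(1)
  g <- dose_grid(array(runif(60, 0, 5), c(3, 4, 5)),
                 spacing = c(1.5, 1, 2), origin = c(-3, 0, 1),
                 axes = c("z", "y", "x"))
  path <- tempfile(fileext = ".json")
  write_dose_grid(g, path)
  h <- read_dose_grid(path)
  expect_identical(h$values, g$values)
  expect_identical(h$spacing, g$spacing)
  expect_identical(h$origin, g$origin)
  expect_identical(h$axes, g$axes)
})

test_that("RT Dose round trip preserves the grid within the scaling quantum", {
  set.seed(2)
  g <- dose_grid(array(runif(5 * 6 * 7, 0, 8), c(5, 6, 7)),
                 spacing = c(1.5, 1.5, 1.5), origin = c(-3, -4, -5))
  path <- tempfile(fileext = ".dcm")
  scaling <- max(g$values) / 1e6
  write_rtdose(g, path, scaling = scaling)
  h <- read_rtdose(path)
  expect_lte(max(abs(h$values - g$values)), scaling)
  expect_equal(h$spacing, g$spacing)
  expect_equal(h$origin, g$origin)
  expect_identical(h$axes, c("z", "y", "x"))
})

test_that("RT Dose scaling is applied: raw 2000 at scaling 0.001 reads 2 Gy", {
  g <- dose_grid(matrix(2, 2, 2), spacing = c(1, 1))
  path <- tempfile(fileext = ".dcm")
  write_rtdose(g, path, scaling = 0.001)   # stored integers are 2000
  h <- read_rtdose(path)
  expect_equal(as.vector(h$values), rep(2, 4), tolerance = 1e-12)
})

test_that("batch_uncertainty matches the standard-error definition", {
  g <- dose_grid(matrix(5, 3, 3), spacing = c(1, 1))
  expect_equal(batch_uncertainty(list(g, g, g)), 0)
  # two batches on effectively one voxel value: SEM = 0.1, mean = 1.1
  b1 <- dose_grid(c(1.0, 1.0), spacing = 1)
  b2 <- dose_grid(c(1.2, 1.2), spacing = 1)
  expect_equal(batch_uncertainty(list(b1, b2)), 100 * 0.1 / 1.1,
               tolerance = 1e-9)
  # 64 batches of flat dose with 1% noise: SEM ~ 1%/sqrt(64) = 0.125%
  set.seed(3)
  batches <- lapply(1:64, function(i) {
    dose_grid(matrix(10 * (1 + rnorm(400, 0, 0.01)), 20, 20), spacing = c(1, 1))
  })
  expect_equal(batch_uncertainty(batches), 0.125, tolerance = 0.01)
  # invariant under global dose scaling
  scaled <- lapply(batches, function(b) { b$values <- b$values * 3.7; b })
  expect_equal(batch_uncertainty(scaled), batch_uncertainty(batches),
               tolerance = 1e-9)
  expect_error(batch_uncertainty(list(b1)), "at least 2")
  expect_error(batch_uncertainty(list(b1, g)), "identical grid")
})
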