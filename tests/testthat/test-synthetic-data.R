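test_that("generators are bit-identical under a fixed seed", {
  spec <- beam_model_spec(23.0, noise_sigma_percent = 1)
  expect_identical(gen_ocr(spec, seed = 3)$values, gen_ocr(spec, seed = 3)$values)
  pert <- perturbation_spec(gaussian_noise_percent = 1, seed = 5)
  p1 <- gen_dose_pair(c(9, 9), 2, "single-gaussian-target", pert)
  p2 <- gen_dose_pair(c(9, 9), 2, "single-gaussian-target", pert)
  expect_identical(p1$evaluated$values, p2$evaluated$values)
  s1 <- gen_qa_series(qa_series_spec(seed = 11))
  s2 <- gen_qa_series(qa_series_spec(seed = 11))
  expect_identical(s1$series$pass_rate$value, s2$series$pass_rate$value)
})

test_that("generated curves satisfy the scan-curve contract for all field sizes", {
  for (fs in cyberknife_field_sizes()$mlc) {
    spec <- beam_model_spec(fs)
    ocr <- gen_ocr(spec, depth_mm = 50)
    expect_s3_class(ocr, "scan_curve")
    expect_equal(resample_to(ocr, 0), 1, tolerance = 1e-9)
    ddc <- gen_ddc(spec, depths = seq(0, 120, by = 1))
    expect_true(all(ddc$values >= 0))
    expect_identical(ddc$curve_kind, "DDC")
  }
})

test_that("profiles are even and their FWHM matches the analytic root", {
  spec <- beam_model_spec(23.0)
  ocr <- gen_ocr(spec, positions = seq(-40, 40, by = 0.5))
  v <- as.vector(ocr$values)
  expect_equal(v, rev(v), tolerance = 1e-12)
  fw <- ocr_fwhm(spec)
  expect_equal(fw, 23.0, tolerance = 0.1)
  # sampled-curve FWHM (linear interpolation of the half-maximum crossings)
  pos <- grid_axis_coords(ocr, 1)
  above <- v >= 0.5
  i1 <- min(which(above)); i2 <- max(which(above))
  cross <- function(i, j) {
    pos[i] + (0.5 - v[i]) * (pos[j] - pos[i]) / (v[j] - v[i])
  }
  fw_sampled <- cross(i2, i2 + 1) - cross(i1, i1 - 1)
  expect_lt(abs(fw_sampled - fw), ocr$spacing)   # within one grid step
})

test_that("depth-dose curves honour the reference-depth and maximum contracts", {
  spec <- beam_model_spec(15.4)
  ddc <- gen_ddc(spec, depths = seq(0, 200, by = 0.5))
  ofv <- spec$of_curve(15.4)
  expect_equal(resample_to(ddc, spec$d_ref_mm), ofv, tolerance = 1e-12)
  zmax <- ddc_zmax(spec)
  depths <- grid_axis_coords(ddc, 1)
  expect_lt(abs(depths[which.max(ddc$values)] - zmax), ddc$spacing + 1e-9)
  # doubling the output factor scales the whole curve without changing shape
  spec2 <- beam_model_spec(15.4, of_curve = function(fs) 2 * fs^2 / (fs^2 + 3.5^2))
  ddc2 <- gen_ddc(spec2, depths = seq(0, 200, by = 0.5))
  expect_equal(as.vector(ddc2$values), 2 * as.vector(ddc$values),
               tolerance = 1e-12)
})

test_that("a null perturbation is an exact fixed point of the pipeline", {
  p <- gen_dose_pair(c(9, 9, 9), 2, "single-gaussian-target", perturbation_spec())
  expect_identical(p$reference$values, p$evaluated$values)
  r <- gamma_index(p$reference, p$evaluated)
  expect_equal(max(r$gamma_map, na.rm = TRUE), 0)
  expect_equal(r$pass_rate, 100)
})

test_that("a pure 2% scale on a flat pattern lands exactly on the gamma boundary", {
  p <- gen_dose_pair(c(9, 9), 2, "flat", perturbation_spec(global_scale_percent = 2))
  r <- gamma_index(p$reference, p$evaluated,
                   gamma_criteria(2, 1, cutoff_percent = 10))
  expect_equal(range(r$gamma_map, na.rm = TRUE), c(1, 1), tolerance = 1e-9)
  expect_equal(r$pass_rate, 100)
})

test_that("a shifted target's engine pass rate matches the 3D oracle", {
  p <- gen_dose_pair(c(7, 7, 7), 3, "single-gaussian-target",
                     perturbation_spec(shift_mm = c(1, 0, 0)))
  e <- compare_plan(p$reference, p$evaluated, "3d-idc")
  o <- gamma_oracle(p$reference, p$evaluated,
                    gamma_criteria(2, 1, cutoff_percent = 10))
  expect_lte(abs(e$pass_rate - o$pass_rate), 0.1)
})

test_that("shift beyond the grid margin is rejected", {
  expect_error(gen_dose_pair(c(9, 9), 2, "flat",
                             perturbation_spec(shift_mm = c(10, 0))),
               "margin")
})

test_that("the detector-array mask samples two pitch zones", {
  g <- dose_grid(array(1, c(45, 45)), spacing = c(2.5, 2.5),
                 origin = c(-55, -55))
  m <- srs_detector_mask(g)
  pts <- grid_node_coords(g)
  # high-resolution core: every 2.5 mm node inside 55x55 is sampled
  core <- abs(pts[, 1]) <= 27.5 & abs(pts[, 2]) <= 27.5
  expect_true(all(m[core]))
  # outer zone: only the 5 mm lattice is sampled
  outer <- !core
  on5 <- pts[, 1] %% 5 == 0 & pts[, 2] %% 5 == 0
  expect_equal(as.vector(m)[outer], on5[outer])
})

test_that("QA series generation respects bounds, injections and labels", {
  gs <- gen_qa_series(qa_series_spec(
    n_plans = 30,
    baseline = list(pass_rate = c(mean = 98, sd = 0)),
    injected = data.frame(index = c(5, 20), metric = "pass_rate", shift = -10),
    seed = 2))
  x <- gs$series$pass_rate$value
  expect_equal(x[-c(5, 20)], rep(98, 28))
  expect_equal(x[c(5, 20)], c(88, 88))
  expect_equal(gs$injected_plan_ids, c("P005", "P020"))
  # zero-sigma, no injections: constant series
  const <- gen_qa_series(qa_series_spec(
    n_plans = 10, baseline = list(mean_gamma = c(mean = 0.3, sd = 0)), seed = 1))
  expect_equal(const$series$mean_gamma$value, rep(0.3, 10))
  # truncation to the metric's physical bounds
  hi <- gen_qa_series(qa_series_spec(
    n_plans = 10, baseline = list(pass_rate = c(mean = 99.9, sd = 2)), seed = 3))
  expect_true(all(hi$series$pass_rate$value <= 100))
})
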