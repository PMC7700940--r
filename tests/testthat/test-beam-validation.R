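test_that("detector correction multiplies by the (interpolated) factor", {
  k1 <- data.frame(field_size_mm = c(5, 7.5, 10), k = c(1, 1, 1))
  expect_equal(apply_detector_correction(0.7, k1, 7.5), 0.7)
  k2 <- data.frame(field_size_mm = c(5, 7.5), k = c(0.95, 0.97))
  expect_equal(apply_detector_correction(0.700, k2, 5), 0.665)
  expect_equal(apply_detector_correction(1, k2, 6.25), 0.96)  # midpoint
  expect_error(apply_detector_correction(0.7, k2, 12), "extrapolation")
  # named-vector form of the table
  expect_equal(apply_detector_correction(0.700, c(`5` = 0.95, `7.5` = 0.97), 5),
               0.665)
})

test_that("output-factor records carry a consistent signed relative error", {
  r <- output_factor_records("fixed", c(5, 10), c(0.68, 0.85), c(0.7015, 0.84))
  expect_equal(r$relative_error_percent,
               100 * (r$of_calculated - r$of_measured) / r$of_measured,
               tolerance = 1e-9)
  expect_error(output_factor_records("fixed", 5, -0.1, 0.7))
})

test_that("of_summary bins errors by tolerance per collimator", {
  r <- output_factor_records(c("fixed", "fixed"), c(10, 20),
                             c(1, 1), c(1.01, 0.99))
  s <- of_summary(r)
  expect_equal(s$mean_error, 0, tolerance = 1e-9)
  expect_equal(s$min_error, -1, tolerance = 1e-9)
  expect_equal(s$max_error, 1, tolerance = 1e-9)
  expect_equal(s$within_1pct, 2L)
  expect_equal(s$within_2pct, 2L)

  # a single 3.16% deviation falls outside both tolerance bins
  r1 <- output_factor_records("fixed", 5, 1, 1.0316)
  s1 <- of_summary(r1)
  expect_equal(s1$within_1pct, 0L)
  expect_equal(s1$within_2pct, 0L)
  expect_equal(s1$min_error, 3.16, tolerance = 1e-9)
  expect_equal(s1$max_error, 3.16, tolerance = 1e-9)

  # randomized records: counts match direct enumeration, monotone in tolerance
  set.seed(10)
  err <- runif(12, -3, 3)
  rr <- output_factor_records(rep("iris", 12), rep(cyberknife_field_sizes()$iris, 1),
                              rep(1, 12), 1 + err / 100)
  ss <- of_summary(rr, tolerances = c(0.5, 1, 2, 3))
  expect_equal(ss$within_1pct, sum(abs(err) <= 1 + 1e-9))
  expect_equal(ss$within_2pct, sum(abs(err) <= 2 + 1e-9))
  expect_true(ss$within_0.5pct <= ss$within_1pct &&
                ss$within_1pct <= ss$within_2pct &&
                ss$within_2pct <= ss$within_3pct)
})

test_that("identical curves pass 100% for any criteria", {
  ddc <- gen_ddc(beam_model_spec(23.0), depths = seq(0, 200, by = 1))
  for (cr in list(gamma_criteria(1, 0.5, cutoff_percent = 0),
                  gamma_criteria(2, 0.5, cutoff_percent = 0))) {
    cc <- validate_curve(ddc, ddc, cr)
    expect_equal(cc$pass_rate_percent, 100)
    expect_equal(cc$points_evaluated, 201L)
  }
})

test_that("a global 3% DDC scale error fails widely under Gamma(2,0.5)", {
  spec <- beam_model_spec(15.4)
  meas <- gen_ddc(spec, depths = seq(0, 250, by = 1))
  calc <- meas
  calc$values <- calc$values * 1.03
  cr <- gamma_criteria(2, 0.5, cutoff_percent = 0)
  cc <- validate_curve(meas, calc, cr)
  expect_lt(cc$pass_rate_percent, 80)
  # agrees with the dense 1D oracle on the same absolute-dose comparison
  o <- gamma_oracle(meas, calc, cr)
  expect_equal(cc$pass_rate_percent, o$pass_rate, tolerance = 0.11)
})

test_that("OCR comparison normalises both curves to the central axis", {
  spec <- beam_model_spec(23.0)
  meas <- gen_ocr(spec, depth_mm = 15)
  calc <- gen_ocr(beam_model_spec(23.0, penumbra_sigma_mm = 2.55), depth_mm = 15)
  cr <- gamma_criteria(1, 0.5, cutoff_percent = 0)
  base <- validate_curve(meas, calc, cr)
  # independent positive rescaling of either curve changes nothing
  calc_scaled <- calc
  calc_scaled$values <- calc$values * 5
  rescaled <- validate_curve(meas, calc_scaled, cr)
  expect_equal(rescaled$pass_rate_percent, base$pass_rate_percent)
  expect_equal(rescaled$mean_gamma, base$mean_gamma, tolerance = 1e-9)
  # a DDC comparison is not invariant to one-sided rescaling
  ddc <- gen_ddc(spec, depths = seq(0, 150, by = 1))
  ddc_s <- ddc
  ddc_s$values <- ddc$values * 1.05
  expect_lt(validate_curve(ddc, ddc_s,
                           gamma_criteria(2, 0.5, cutoff_percent = 0))$pass_rate_percent,
            100)
})

test_that("a sub-criterion penumbra shift passes where the oracle passes", {
  spec <- beam_model_spec(23.0)
  meas <- gen_ocr(spec, depth_mm = 15)
  pos <- grid_axis_coords(meas, 1)
  shifted <- scan_curve(pos, gammaspc:::ocr_shape(spec, pos - 0.3),
                        curve_kind = "OCR", collimator = "mlc",
                        field_size_mm = 23.0, depth_mm = 15, is_relative = TRUE)
  cr <- gamma_criteria(1, 0.5, cutoff_percent = 0)
  cc <- validate_curve(meas, shifted, cr)
  # replicate the CAX normalisation and check against the dense oracle
  nrm <- function(cv) {
    g <- cv
    g$values <- cv$values / resample_to(cv, 0)
    g
  }
  o <- gamma_oracle(nrm(meas), nrm(shifted), cr)
  expect_equal(cc$pass_rate_percent, o$pass_rate, tolerance = 0.11)
})

test_that("the validation report formats mean (min-max) cells", {
  spec <- beam_model_spec(23.0)
  ddc <- gen_ddc(spec, depths = seq(0, 100, by = 1))
  one <- validate_curve(ddc, ddc)
  rep1 <- validation_report(list(one))
  expect_equal(rep1$curves$cell, "100 (100-100)")

  fake <- function(pass) {
    x <- one
    x$pass_rate_percent <- pass
    x
  }
  rep3 <- validation_report(list(fake(35), fake(85), fake(99)))
  expect_equal(rep3$curves$cell, "73 (35-99)")
  expect_equal(rep3$curves$mean_pass, 73)

  # aggregated cells equal direct recomputation from the comparisons
  set.seed(11)
  comps <- lapply(cyberknife_field_sizes()$mlc[1:6], function(fs) {
    sp <- beam_model_spec(fs)
    m <- gen_ddc(sp, depths = seq(0, 120, by = 1))
    cshift <- m
    cshift$values <- m$values * (1 + runif(1, -0.01, 0.01))
    validate_curve(m, cshift, gamma_criteria(2, 0.5, cutoff_percent = 0))
  })
  repn <- validation_report(comps)
  expect_equal(repn$curves$mean_pass,
               mean(vapply(comps, `[[`, 1, "pass_rate_percent")))
})
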