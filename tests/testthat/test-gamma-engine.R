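test_that("gamma of a distribution against itself is identically zero", {
  for (nd in 1:3) {
    p <- smooth_random_pair(nd, seed = 10 + nd, shape = c(25, 9, 6)[nd])
    r <- gamma_index(p$reference, p$reference,
                     gamma_criteria(2, 1, cutoff_percent = 10))
    expect_equal(max(r$gamma_map, na.rm = TRUE), 0)
    expect_equal(r$pass_rate, 100)
    expect_equal(r$mean_gamma, 0)
  }
})

test_that("a flat 2% offset under Gamma(2,.) gives gamma = 1 and passes", {
  ref <- dose_grid(array(10, c(8, 8)), spacing = c(2, 2))
  ev <- ref
  ev$values[] <- 10.2
  for (fun in list(gamma_index, gamma_oracle)) {
    r <- fun(ref, ev, gamma_criteria(2, 0.5, cutoff_percent = 0))
    expect_equal(as.vector(r$gamma_map), rep(1, 64), tolerance = 1e-9)
    expect_equal(r$pass_rate, 100)
  }
  # local normalization agrees on a flat field
  rl <- gamma_index(ref, ev, gamma_criteria(2, 0.5, normalization = "local",
                                            cutoff_percent = 0))
  expect_equal(as.vector(rl$gamma_map), rep(1, 64), tolerance = 1e-9)
})

test_that("a ramp shifted by exactly the DTA criterion sits at the pass boundary", {
  x <- seq(0, 50, by = 1)
  ref <- dose_grid(1 + 0.1 * x, spacing = 1)
  ev <- dose_grid(1 + 0.1 * (x - 1), spacing = 1)   # ramp shifted by 1 mm
  cr <- gamma_criteria(2, 1, cutoff_percent = 10)
  e <- gamma_index(ref, ev, cr)
  o <- gamma_oracle(ref, ev, cr)
  interior <- 10:40
  expect_true(all(e$gamma_map[interior] <= 1 + 0.01))
  expect_lte(max(abs(e$gamma_map - o$gamma_map), na.rm = TRUE), 0.01)
})

test_that("engine and dense oracle agree on randomized instances", {
  worst_g <- 0
  worst_p <- 0
  for (k in 1:6) {
    p <- smooth_random_pair(1, seed = 500 + k, shape = 81, spacing = 1,
                            shift_max = 0.7, scale_max = 2)
    cr <- gamma_criteria(c(1, 2, 3)[1 + k %% 3], c(0.5, 1, 2)[1 + k %% 3],
                         cutoff_percent = 10)
    e <- gamma_index(p$reference, p$evaluated, cr)
    o <- gamma_oracle(p$reference, p$evaluated, cr)
    worst_g <- max(worst_g, max(abs(e$gamma_map - o$gamma_map), na.rm = TRUE))
    worst_p <- max(worst_p, abs(e$pass_rate - o$pass_rate))
  }
  p <- smooth_random_pair(2, seed = 42, shape = 11)
  e <- gamma_index(p$reference, p$evaluated, gamma_criteria(2, 1, cutoff_percent = 20))
  o <- gamma_oracle(p$reference, p$evaluated, gamma_criteria(2, 1, cutoff_percent = 20))
  worst_g <- max(worst_g, max(abs(e$gamma_map - o$gamma_map), na.rm = TRUE))
  worst_p <- max(worst_p, abs(e$pass_rate - o$pass_rate))
  expect_lt(worst_g, 0.01)
  expect_lte(worst_p, 0.1)
})

test_that("global-max normalization is invariant under a common dose scale", {
  p <- smooth_random_pair(2, seed = 77, shape = 11)
  cr <- gamma_criteria(2, 1, cutoff_percent = 10)
  r1 <- gamma_index(p$reference, p$evaluated, cr)
  ref2 <- p$reference; ref2$values <- ref2$values * 3.7
  ev2 <- p$evaluated; ev2$values <- ev2$values * 3.7
  r2 <- gamma_index(ref2, ev2, cr)
  expect_equal(r2$gamma_map, r1$gamma_map, tolerance = 1e-9)
  expect_identical(r2$evaluated_mask, r1$evaluated_mask)
})

test_that("raising the dose cutoff never enlarges the evaluated mask", {
  p <- smooth_random_pair(2, seed = 78, shape = 11)
  masks <- lapply(c(0, 10, 30, 60, 90), function(co) {
    gamma_index(p$reference, p$evaluated,
                gamma_criteria(3, 1, cutoff_percent = co))$evaluated_mask
  })
  for (i in 2:length(masks)) {
    expect_true(all(masks[[i - 1]][masks[[i]]]))   # mask_i subset of mask_{i-1}
  }
})

test_that("pass rate is monotone in both criteria (fixed search step in mm)", {
  for (k in 1:3) {
    p <- smooth_random_pair(1 + k %% 2, seed = 90 + k, shape = c(41, 13)[1 + k %% 2],
                            shift_max = 1, scale_max = 3)
    crit <- function(dd, dta) {
      gamma_criteria(dd, dta, cutoff_percent = 10,
                     search_step_fraction = 0.1 / dta)  # step fixed at 0.1 mm
    }
    pr_dd <- vapply(c(1, 2, 4), function(dd) {
      gamma_index(p$reference, p$evaluated, crit(dd, 1))$pass_rate
    }, numeric(1))
    expect_false(is.unsorted(pr_dd))
    pr_dta <- vapply(c(0.5, 1, 2), function(dta) {
      gamma_index(p$reference, p$evaluated, crit(2, dta))$pass_rate
    }, numeric(1))
    expect_false(is.unsorted(pr_dta))
  }
})

test_that("points whose search ball exits the evaluated extent are counted", {
  p <- smooth_random_pair(2, seed = 99, shape = 11)
  r <- gamma_index(p$reference, p$evaluated, gamma_criteria(2, 1, cutoff_percent = 0))
  # reference and evaluated share the extent, so every point within 3 mm of
  # the edge has a truncated search ball
  expect_gt(r$n_boundary, 0)
  expect_lte(r$n_boundary, r$n_evaluated)
})

test_that("degenerate inputs raise the documented errors", {
  g2 <- dose_grid(matrix(1, 3, 3), spacing = c(1, 1))
  g1 <- dose_grid(c(1, 1), spacing = 1)
  expect_error(gamma_index(g2, g1, gamma_criteria()), "dimensionality")
  zero <- dose_grid(matrix(0, 3, 3), spacing = c(1, 1))
  expect_error(gamma_index(zero, zero, gamma_criteria()), "no positive dose")
})

test_that("a 5% scale error on a shallow-gradient dome fails widely", {
  # a broad dome: the 3 mm search radius cannot compensate a 5% global error
  g <- dose_grid(array(0, c(9, 9, 9)), spacing = rep(4, 3), origin = rep(-16, 3))
  g$values[] <- 10 * exp(-rowSums(grid_node_coords(g)^2) / (2 * 60^2))
  ev <- g
  ev$values <- g$values * 1.05
  r <- compare_plan(g, ev, "3d-idc")
  expect_lt(r$pass_rate, 50)
  centre <- which(rowSums(grid_node_coords(g)^2) == 0)
  expect_gt(r$gamma_map[centre], 2)
})

test_that("compare_plan applies the clinical presets and checks dimensionality", {
  p2 <- smooth_random_pair(2, seed = 5, shape = 11)
  r <- compare_plan(p2$reference, p2$reference, mode = "2d-measurement")
  expect_equal(r$pass_rate, 100)
  expect_equal(r$criteria$dose_diff_percent, 2)
  expect_equal(r$criteria$dta_mm, 1)
  expect_equal(r$criteria$cutoff_percent, 10)
  expect_error(compare_plan(p2$reference, p2$evaluated, mode = "3d-idc"),
               "3-axis")
})
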