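# All generators are deterministic under a fixed seed; randomness is scoped
# so the caller's RNG state is left untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Analytic beam-model specification for synthetic scan curves
#'
#' Functional forms are chosen for closed-form ground truth (FWHM, depth of
#' maximum), not as a physical model of the real 6 MV FFF beam: the lateral
#' profile is a sum of two tanh sigmoid edges (one per field edge) and the
#' depth dose a build-up times exponential-falloff product.
#'
#' @param field_size_mm nominal field size (mm).
#' @param collimator collimator system the field size belongs to.
#' @param penumbra_sigma_mm penumbra width parameter of the sigmoid edges
#'   (mm; default 2.5, a typical small-field penumbra scale).
#' @param mu_atten effective attenuation coefficient beyond build-up
#'   (1/mm; default 0.005, ~0.5%/mm falloff).
#' @param mu_buildup build-up rate (1/mm; default 0.26, placing the depth of
#'   maximum near 15 mm).
#' @param d_ref_mm reference depth (mm; 15 mm for all collimators).
#' @param of_curve monotone non-decreasing field-size -> output-factor
#'   function; default `FS^2 / (FS^2 + 3.5^2)` (~0.67 at 5 mm, ~1 at 60 mm).
#' @param noise_sigma_percent multiplicative Gaussian noise level for
#'   generated curves (percent; 0 = noise-free).
#' @return object of class `beam_model_spec`.
#' @export
beam_model_spec <- function(field_size_mm, collimator = "mlc",
                            penumbra_sigma_mm = 2.5,
                            mu_atten = 0.005, mu_buildup = 0.26,
                            d_ref_mm = 15,
                            of_curve = function(fs) fs^2 / (fs^2 + 3.5^2),
                            noise_sigma_percent = 0) {
  stopifnot(field_size_mm > 0, penumbra_sigma_mm > 0,
            mu_atten > 0, mu_buildup > 0, d_ref_mm > 0,
            noise_sigma_percent >= 0)
  structure(
    list(field_size_mm = field_size_mm, collimator = collimator,
         penumbra_sigma_mm = penumbra_sigma_mm,
         mu_atten = mu_atten, mu_buildup = mu_buildup, d_ref_mm = d_ref_mm,
         of_curve = of_curve, noise_sigma_percent = noise_sigma_percent),
    class = "beam_model_spec"
  )
}

# unnormalised analytic profile: a tanh sigmoid edge on each side of the
# field; the sum is 2*tanh(hw/s) on axis and falls to 0 far off axis
ocr_shape <- function(spec, x) {
  hw <- spec$field_size_mm / 2
  s <- spec$penumbra_sigma_mm
  (tanh((hw - x) / s) + tanh((hw + x) / s)) / 2
}

#' Generate a synthetic off-centre-ratio curve
#'
#' `OCR(x)` is the two-sided sigmoid profile normalised to 1.0 on the central
#' axis; it is an even function of `x` when noise is off.
#'
#' @param spec a [beam_model_spec()].
#' @param depth_mm measurement depth metadata (mm).
#' @param positions off-axis positions (mm); must cover at least
#'   `±(field_size/2 + 5·penumbra_sigma)`.
#' @param seed optional seed for the noise.
#' @return a [scan_curve()] of kind `"OCR"` (relative dose).
#' @export
gen_ocr <- function(spec, depth_mm = 15, positions = NULL, seed = NULL) {
  stopifnot(inherits(spec, "beam_model_spec"))
  cover <- spec$field_size_mm / 2 + 5 * spec$penumbra_sigma_mm
  if (is.null(positions)) positions <- seq(-ceiling(cover), ceiling(cover), by = 0.5)
  if (min(positions) > -cover + 1e-9 || max(positions) < cover - 1e-9) {
    stop("positions must cover at least +/-", cover, " mm for this field size")
  }
  v <- ocr_shape(spec, positions) / ocr_shape(spec, 0)
  if (spec$noise_sigma_percent > 0) {
    v <- with_seed(seed, v * (1 + stats::rnorm(length(v), 0,
                                               spec$noise_sigma_percent / 100)))
    v <- pmax(v, 0)
    v <- v / v[which.min(abs(positions))]   # keep the CAX normalisation
  }
  scan_curve(positions, v, curve_kind = "OCR", collimator = spec$collimator,
             field_size_mm = spec$field_size_mm, depth_mm = depth_mm,
             is_relative = TRUE)
}

#' Analytic full width at half maximum of the synthetic profile
#'
#' Root of `OCR(x) = 1/2` found on the analytic (noise-free, normalised)
#' form; the FWHM is twice that root. For field sizes well above the
#' penumbra width this is very close to the nominal field size.
#'
#' @param spec a [beam_model_spec()].
#' @return FWHM in mm.
#' @export
ocr_fwhm <- function(spec) {
  f <- function(x) ocr_shape(spec, x) / ocr_shape(spec, 0) - 0.5
  upper <- spec$field_size_mm / 2 + 20 * spec$penumbra_sigma_mm
  2 * stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' Generate a synthetic depth-dose curve
#'
#' `D(z) = OF(FS) · (1 - exp(-mu_b z)) · exp(-mu z) / norm`, normalised so
#' that the dose at the reference depth equals the output factor. The curve
#' includes the build-up region; its maximum sits at the closed-form depth
#' [ddc_zmax()].
#'
#' @param spec a [beam_model_spec()].
#' @param depths depth samples (mm), starting at 0.
#' @param seed optional seed for the noise.
#' @return a [scan_curve()] of kind `"DDC"` (absolute dose).
#' @export
gen_ddc <- function(spec, depths = seq(0, 300, by = 1), seed = NULL) {
  stopifnot(inherits(spec, "beam_model_spec"))
  if (abs(depths[1L]) > 1e-9) stop("depths must start at 0 (water surface)")
  shape <- function(z) (1 - exp(-spec$mu_buildup * z)) * exp(-spec$mu_atten * z)
  ofv <- spec$of_curve(spec$field_size_mm)
  v <- ofv * shape(depths) / shape(spec$d_ref_mm)
  if (spec$noise_sigma_percent > 0) {
    v <- with_seed(seed, v * (1 + stats::rnorm(length(v), 0,
                                               spec$noise_sigma_percent / 100)))
    v <- pmax(v, 0)
  }
  scan_curve(depths, v, curve_kind = "DDC", collimator = spec$collimator,
             field_size_mm = spec$field_size_mm)
}

#' Closed-form depth of maximum of the synthetic depth-dose curve
#' @param spec a [beam_model_spec()].
#' @return depth of maximum dose in mm: `log(1 + mu_b/mu) / mu_b`.
#' @export
ddc_zmax <- function(spec) {
  log(1 + spec$mu_buildup / spec$mu_atten) / spec$mu_buildup
}

#' Perturbation specification for paired dose grids
#'
#' Controlled discrepancies applied to a reference distribution, in the fixed
#' order scale -> shift -> blob -> noise, emulating the failure modes seen in
#' clinical QA: a global dose scaling factor, a rigid spatial misplacement,
#' a localised dose error, and stochastic noise.
#'
#' @param global_scale_percent global dose scaling (+2 means evaluated =
#'   1.02 × reference).
#' @param shift_mm rigid shift per axis (mm), recycled to the grid
#'   dimensionality.
#' @param gaussian_noise_percent multiplicative Gaussian noise sigma
#'   (percent of local dose).
#' @param blob optional local error: a list with `centre` (mm), `radius_mm`
#'   (> 0) and `amplitude_percent` (peak multiplicative error).
#' @param seed seed fixing all randomness of the pair generation.
#' @return object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(global_scale_percent = 0, shift_mm = 0,
                              gaussian_noise_percent = 0, blob = NULL,
                              seed = 1L) {
  if (!is.null(blob)) {
    stopifnot(is.list(blob), !is.null(blob$centre), blob$radius_mm > 0,
              !is.null(blob$amplitude_percent))
  }
  stopifnot(gaussian_noise_percent >= 0)
  structure(
    list(global_scale_percent = global_scale_percent, shift_mm = shift_mm,
         gaussian_noise_percent = gaussian_noise_percent, blob = blob,
         seed = seed),
    class = "perturbation_spec"
  )
}

dose_pattern <- function(pattern, pts, extent, target_sigma_mm = NULL) {
  peak <- 10  # Gy
  sigma <- if (is.null(target_sigma_mm)) max(min(extent) / 6, 3) else target_sigma_mm
  if (pattern == "flat") return(rep(peak, nrow(pts)))
  g <- function(centre, amp, sd) {
    d2 <- rep(0, nrow(pts))
    for (a in seq_len(ncol(pts))) d2 <- d2 + (pts[, a] - centre[a])^2
    amp * exp(-d2 / (2 * sd^2))
  }
  if (pattern == "single-gaussian-target") {
    g(rep(0, ncol(pts)), peak, sigma)
  } else {  # dual-target
    off <- min(extent) / 5
    g(rep(-off, ncol(pts)), peak, sigma * 0.8) +
      g(rep(off, ncol(pts)), 0.7 * peak, sigma * 0.6)
  }
}

#' Generate a reference/evaluated dose-grid pair with known discrepancies
#'
#' The reference is an analytic dose pattern sampled on a centred grid; the
#' evaluated distribution is the reference transformed by global scaling,
#' rigid shift (multilinear interpolation of the analytically enlarged,
#' scaled reference), localised blob error and multiplicative noise, in that
#' fixed order, reproducibly under the perturbation seed.
#'
#' @param shape integer vector of grid dimensions (1-3 axes).
#' @param spacing per-axis spacing (mm), recycled.
#' @param base_pattern `"single-gaussian-target"`, `"dual-target"` or
#'   `"flat"`.
#' @param perturbation a [perturbation_spec()].
#' @param target_sigma_mm optional Gaussian width of the target(s) in mm;
#'   the default (extent/6, at least 3) gives a steep stereotactic-like
#'   target, larger values give shallow-gradient distributions.
#' @return list with [dose_grid()] elements `reference` and `evaluated`.
#' @export
gen_dose_pair <- function(shape, spacing = 1,
                          base_pattern = c("single-gaussian-target",
                                           "dual-target", "flat"),
                          perturbation = perturbation_spec(),
                          target_sigma_mm = NULL) {
  base_pattern <- match.arg(base_pattern)
  stopifnot(inherits(perturbation, "perturbation_spec"))
  shape <- as.integer(shape)
  nd <- length(shape)
  spacing <- rep(as.numeric(spacing), length.out = nd)
  extent <- (shape - 1) * spacing
  origin <- -extent / 2
  shift <- rep(as.numeric(perturbation$shift_mm), length.out = nd)
  if (any(abs(shift) > extent / 4)) {
    stop("shift exceeds the grid margin (|shift| must be <= extent/4)")
  }
  axes <- switch(nd, "x", c("y", "x"), c("z", "y", "x"))
  ref <- dose_grid(array(0, dim = if (nd == 1L) c(shape, 1)[1L] else shape),
                   spacing = spacing, origin = origin, axes = axes)
  ref$values[] <- dose_pattern(base_pattern, grid_node_coords(ref), extent,
                               target_sigma_mm)

  scale <- 1 + perturbation$global_scale_percent / 100
  if (any(shift != 0)) {
    # enlarge the sampled reference so shifted queries never extrapolate
    pad <- ceiling(abs(shift) / spacing) + 1L
    big_shape <- shape + 2L * pad
    big <- dose_grid(array(0, dim = if (nd == 1L) big_shape[1L] else big_shape),
                     spacing = spacing, origin = origin - pad * spacing,
                     axes = axes)
    big$values[] <- scale * dose_pattern(base_pattern, grid_node_coords(big),
                                         extent, target_sigma_mm)
    q <- sweep(grid_node_coords(ref), 2L, shift, "-")
    ev_vals <- resample_to(big, q)
  } else {
    ev_vals <- scale * as.vector(ref$values)
  }
  if (!is.null(perturbation$blob)) {
    b <- perturbation$blob
    centre <- rep(as.numeric(b$centre), length.out = nd)
    d2 <- rep(0, length(ev_vals))
    pts <- grid_node_coords(ref)
    for (a in seq_len(nd)) d2 <- d2 + (pts[, a] - centre[a])^2
    ev_vals <- ev_vals *
      (1 + b$amplitude_percent / 100 * exp(-d2 / (2 * (b$radius_mm / 2)^2)))
  }
  if (perturbation$gaussian_noise_percent > 0) {
    ev_vals <- with_seed(perturbation$seed, {
      ev_vals * (1 + stats::rnorm(length(ev_vals), 0,
                                  perturbation$gaussian_noise_percent / 100))
    })
    ev_vals <- pmax(ev_vals, 0)
  }
  ev <- ref
  ev$values[] <- ev_vals
  list(reference = ref, evaluated = ev)
}

#' Detector-array sampling mask for a 2D dose plane
#'
#' Emulates the chamber layout of a 2D SRS detector array: positions on a
#' 2.5 mm pitch inside the central high-resolution square and on a 5 mm pitch
#' in the remainder of the array area; grid nodes elsewhere are unsampled.
#'
#' @param grid a 2D [dose_grid()] with axes (y, x), centred coordinates.
#' @param hires_mm side of the central high-resolution square (default 55).
#' @param total_mm side of the full array area (default 110).
#' @return logical matrix (same shape as the grid) marking sampled nodes.
#' @export
srs_detector_mask <- function(grid, hires_mm = 55, total_mm = 110) {
  stopifnot(grid_ndim(grid) == 2L)
  pts <- grid_node_coords(grid)
  on_pitch <- function(x, pitch) abs(x / pitch - round(x / pitch)) < 1e-6
  inside_tot <- abs(pts[, 1L]) <= total_mm / 2 + 1e-9 &
    abs(pts[, 2L]) <= total_mm / 2 + 1e-9
  inside_hr <- abs(pts[, 1L]) <= hires_mm / 2 + 1e-9 &
    abs(pts[, 2L]) <= hires_mm / 2 + 1e-9
  m <- ifelse(inside_hr,
              on_pitch(pts[, 1L], 2.5) & on_pitch(pts[, 2L], 2.5),
              inside_tot & on_pitch(pts[, 1L], 5) & on_pitch(pts[, 2L], 5))
  array(m, dim = dim(grid$values))
}

#' Specification for a synthetic chronological QA series
#'
#' @param n_plans number of plans in the series.
#' @param baseline named list of metrics, each `c(mean =, sd =)`; defaults
#'   emulate a well-behaved IDC process (pass rate ~98%, mean gamma ~0.27).
#' @param injected optional data frame with columns `index`, `metric`,
#'   `shift` (metric units) describing out-of-control plans.
#' @param machine_id machine identifier.
#' @param seed seed fixing the series.
#' @return object of class `qa_series_spec`.
#' @export
qa_series_spec <- function(n_plans = 84,
                           baseline = list(pass_rate = c(mean = 98, sd = 1.5),
                                           mean_gamma = c(mean = 0.27, sd = 0.045)),
                           injected = NULL, machine_id = "CK1", seed = 1L) {
  stopifnot(n_plans >= 3L)
  for (b in baseline) stopifnot(b[["sd"]] >= 0)
  if (!is.null(injected)) {
    stopifnot(all(c("index", "metric", "shift") %in% names(injected)),
              all(injected$index >= 1L), all(injected$index <= n_plans),
              all(injected$metric %in% names(baseline)))
  }
  structure(
    list(n_plans = n_plans, baseline = baseline, injected = injected,
         machine_id = machine_id, seed = seed),
    class = "qa_series_spec"
  )
}

metric_bounds <- function(metric) {
  if (metric == "pass_rate") c(0, 100) else c(0, Inf)
}

#' Generate a synthetic chronological QA series with ground truth
#'
#' Baseline values are drawn i.i.d. Gaussian per metric and truncated to the
#' metric's physical bounds; the injected plans are then shifted by the
#' specified amounts (and re-truncated). The injected plan ids are returned
#' as ground-truth labels.
#'
#' @param spec a [qa_series_spec()].
#' @return list with `series` (named list of [qa_series()], one per metric)
#'   and `injected_plan_ids` (character).
#' @export
gen_qa_series <- function(spec) {
  stopifnot(inherits(spec, "qa_series_spec"))
  ids <- sprintf("P%03d", seq_len(spec$n_plans))
  series <- with_seed(spec$seed, {
    lapply(names(spec$baseline), function(mname) {
      b <- spec$baseline[[mname]]
      bounds <- metric_bounds(mname)
      x <- stats::rnorm(spec$n_plans, b[["mean"]], b[["sd"]])
      if (!is.null(spec$injected)) {
        inj <- spec$injected[spec$injected$metric == mname, , drop = FALSE]
        x[inj$index] <- x[inj$index] + inj$shift
      }
      x <- pmin(pmax(x, bounds[1L]), bounds[2L])
      qa_series(x, plan_id = ids, machine_id = spec$machine_id,
                metric_name = mname)
    })
  })
  names(series) <- names(spec$baseline)
  inj_ids <- if (is.null(spec$injected)) character(0)
             else unique(ids[sort(unique(spec$injected$index))])
  list(series = series, injected_plan_ids = inj_ids)
}
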