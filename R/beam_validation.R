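#' Output-factor comparison records
#'
#' One record per collimator/field-size combination, holding the measured and
#' calculated output factor and their signed relative error
#' `100 * (calculated - measured) / measured` (so a negative error means the
#' calculation under-reads).
#'
#' @param collimator character vector (`"fixed"`, `"iris"`, `"mlc"`).
#' @param field_size_mm nominal field sizes (mm).
#' @param of_measured,of_calculated dimensionless output factors (> 0).
#' @param machine_id optional machine identifier(s).
#' @return a data frame of class `of_records` with column
#'   `relative_error_percent` added.
#' @export
output_factor_records <- function(collimator, field_size_mm,
                                  of_measured, of_calculated,
                                  machine_id = "CK1") {
  stopifnot(all(of_measured > 0), all(of_calculated > 0))
  collimator <- match.arg(collimator, c("fixed", "iris", "mlc"),
                          several.ok = TRUE)
  df <- data.frame(
    machine_id = machine_id, collimator = collimator,
    field_size_mm = as.numeric(field_size_mm),
    of_measured = as.numeric(of_measured),
    of_calculated = as.numeric(of_calculated),
    stringsAsFactors = FALSE
  )
  df$relative_error_percent <-
    100 * (df$of_calculated - df$of_measured) / df$of_measured
  class(df) <- c("of_records", "data.frame")
  df
}

#' Apply a small-field detector-response correction
#'
#' Multiplies a raw (diode-measured) output factor by the detector correction
#' factor for the field size, linearly interpolated between tabulated sizes.
#' Correction factors for small-field diode over-response are taken from the
#' literature and supplied by the user as a table.
#'
#' @param of_raw raw output factor(s).
#' @param k_table data frame with columns `field_size_mm` and `k`, or a named
#'   numeric vector (names = field sizes in mm).
#' @param field_size_mm field size(s) at which to correct; must lie within
#'   the tabulated range (no extrapolation).
#' @return corrected output factor(s) `of_raw * k(field_size)`.
#' @export
apply_detector_correction <- function(of_raw, k_table, field_size_mm) {
  if (is.numeric(k_table) && !is.null(names(k_table))) {
    k_table <- data.frame(field_size_mm = as.numeric(names(k_table)),
                          k = as.numeric(k_table))
  }
  stopifnot(is.data.frame(k_table),
            all(c("field_size_mm", "k") %in% names(k_table)))
  rng <- range(k_table$field_size_mm)
  if (any(field_size_mm < rng[1L] - 1e-9) || any(field_size_mm > rng[2L] + 1e-9)) {
    stop("field size outside the correction-factor table range [",
         rng[1L], ", ", rng[2L], "] mm; extrapolation is not allowed")
  }
  k <- stats::approx(k_table$field_size_mm, k_table$k,
                     xout = field_size_mm, rule = 1)$y
  of_raw * k
}

#' Per-collimator output-factor summary
#'
#' Mean signed relative error with its min-max range and, for each tolerance,
#' the count of records whose absolute error is within it.
#'
#' @param records an [output_factor_records()] data frame.
#' @param tolerances percent tolerances to bin by (default 1% and 2%).
#' @param by grouping columns (default collimator within machine).
#' @return data frame, one row per group: `n`, `mean_error`, `min_error`,
#'   `max_error`, and one `within_<t>pct` count column per tolerance.
#' @export
of_summary <- function(records, tolerances = c(1, 2),
                       by = c("machine_id", "collimator")) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(lv) {
    g <- records[key == lv, , drop = FALSE]
    err <- g$relative_error_percent
    row <- g[1L, by, drop = FALSE]
    row$n <- nrow(g)
    row$mean_error <- mean(err)
    row$min_error <- min(err)
    row$max_error <- max(err)
    for (t in tolerances) {
      row[[sprintf("within_%gpct", t)]] <- sum(abs(err) <= t + 1e-9)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate a calculated scan curve against a measurement by 1D gamma
#'
#' Compares a calculated depth-dose curve or off-centre ratio to its
#' measured counterpart over their common position interval (for DDCs this
#' includes the build-up region). DDCs are compared in absolute dose with the
#' dose-difference criterion normalised to the global maximum of the measured
#' curve; OCR and cross-profile pairs are first normalised to their
#' central-axis (position 0) value, interpolated, before the criteria are
#' applied. The measured curve is the gamma reference, so the pass-rate
#' denominator counts measured samples inside the common interval.
#'
#' @param measured,calculated [scan_curve()] objects of the same kind.
#' @param criteria a [gamma_criteria()]; the water-tank comparisons use
#'   `Γ(1, 0.5)` for OCRs and `Γ(2, 0.5)` for DDCs, with no dose cutoff.
#' @return object of class `curve_comparison`: curve metadata, criteria,
#'   `pass_rate_percent`, `mean_gamma` and `points_evaluated`.
#' @export
validate_curve <- function(measured, calculated,
                           criteria = gamma_criteria(dose_diff_percent = 2,
                                                     dta_mm = 0.5,
                                                     cutoff_percent = 0)) {
  stopifnot(inherits(measured, "scan_curve"), inherits(calculated, "scan_curve"))
  if (!identical(measured$curve_kind, calculated$curve_kind)) {
    stop("curves must share curve_kind")
  }
  lo <- max(measured$origin, calculated$origin)
  hi <- min(measured$origin + (length(measured$values) - 1) * measured$spacing,
            calculated$origin + (length(calculated$values) - 1) * calculated$spacing)
  if (hi <= lo) stop("curves have disjoint position ranges")

  ref <- measured
  ev <- calculated
  if (measured$curve_kind != "DDC") {
    # normalise both to the central-axis value
    norm_to_cax <- function(cv) {
      cax <- resample_to(cv, 0)
      if (!is.finite(cax) || cax <= 0) stop("central-axis value must be positive")
      g <- cv
      g$values <- cv$values / cax
      g$is_relative <- TRUE
      g
    }
    ref <- norm_to_cax(ref)
    ev <- norm_to_cax(ev)
  }
  # restrict the reference to the common interval (uniform grid preserved)
  pos <- grid_axis_coords(ref, 1L)
  keep <- pos >= lo - 1e-9 & pos <= hi + 1e-9
  if (sum(keep) < 2L) stop("fewer than 2 measured samples in the common interval")
  ref_c <- dose_grid(as.vector(ref$values)[keep], spacing = ref$spacing,
                     origin = pos[keep][1L], axes = ref$axes,
                     is_relative = ref$is_relative)
  res <- gamma_index(ref_c, ev, criteria)
  structure(
    list(curve_kind = measured$curve_kind, collimator = measured$collimator,
         field_size_mm = measured$field_size_mm, depth_mm = measured$depth_mm,
         machine_id = measured$machine_id, criteria = criteria,
         pass_rate_percent = res$pass_rate, mean_gamma = res$mean_gamma,
         points_evaluated = res$n_evaluated, gamma = res),
    class = "curve_comparison"
  )
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf(
    "<curve_comparison> %s %s FS %g mm, Gamma(%g%%, %g mm): pass %.1f%% (%d points)\n",
    x$curve_kind, x$collimator, x$field_size_mm,
    x$criteria$dose_diff_percent, x$criteria$dta_mm,
    x$pass_rate_percent, x$points_evaluated))
  invisible(x)
}

#' Beam-model validation report
#'
#' Aggregates 1D curve comparisons per collimator × curve kind × criteria
#' into mean (min-max) pass rates, the cell structure of a commissioning
#' report table, alongside the per-collimator output-factor summary.
#'
#' @param comparisons list of [validate_curve()] results.
#' @param of_records optional [output_factor_records()] for the OF section.
#' @param by_depth if `TRUE`, OCR cells are additionally split by depth
#'   instead of pooling all depths per collimator (default pools).
#' @return list with data frames `curves` (columns `collimator`,
#'   `curve_kind`, `criteria`, `n`, `mean_pass`, `min_pass`, `max_pass`,
#'   `cell` formatted as `"mean (min-max)"`) and `output_factors` (or `NULL`).
#' @export
validation_report <- function(comparisons, of_records = NULL,
                              by_depth = FALSE) {
  stopifnot(length(comparisons) >= 1L)
  df <- do.call(rbind, lapply(comparisons, function(cc) {
    data.frame(
      machine_id = cc$machine_id, collimator = cc$collimator,
      curve_kind = cc$curve_kind,
      depth_mm = cc$depth_mm,
      criteria = sprintf("Gamma(%g,%g)", cc$criteria$dose_diff_percent,
                         cc$criteria$dta_mm),
      pass = cc$pass_rate_percent, stringsAsFactors = FALSE
    )
  }))
  by <- c("machine_id", "collimator", "curve_kind", "criteria")
  if (by_depth) by <- c(by, "depth_mm")
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(lv) {
    g <- df[key == lv, , drop = FALSE]
    row <- g[1L, by, drop = FALSE]
    row$n <- nrow(g)
    row$mean_pass <- mean(g$pass)
    row$min_pass <- min(g$pass)
    row$max_pass <- max(g$pass)
    row$cell <- sprintf("%.0f (%.0f-%.0f)", mean(g$pass), min(g$pass), max(g$pass))
    row
  })
  curves <- do.call(rbind, rows)
  rownames(curves) <- NULL
  list(
    curves = curves,
    output_factors = if (!is.null(of_records)) of_summary(of_records) else NULL
  )
}
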