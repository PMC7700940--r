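#' Chronological QA metric series
#'
#' An ordered record of one per-plan QA metric for one machine/process, the
#' individuals (`x_i`) charted by the SPC functions.
#'
#' @param values metric values in chronological order (pass rates in percent,
#'   or mean gamma).
#' @param plan_id plan identifiers (default `"P001"`, `"P002"`, ...).
#' @param timestamp optional timestamps; must be non-decreasing.
#' @param machine_id machine identifier.
#' @param metric_name `"pass_rate"`, `"mean_gamma"`, or another metric name.
#' @return a `qa_series`: a data frame with columns `plan_id`, `timestamp`,
#'   `machine_id`, `metric_name`, `value`.
#' @export
qa_series <- function(values, plan_id = NULL, timestamp = NULL,
                      machine_id = "CK1", metric_name = "pass_rate") {
  values <- as.numeric(values)
  n <- length(values)
  if (any(!is.finite(values))) stop("metric values must be finite")
  if (metric_name == "pass_rate" && (any(values < 0) || any(values > 100))) {
    stop("pass_rate values must lie in [0, 100]")
  }
  if (metric_name == "mean_gamma" && any(values < 0)) {
    stop("mean_gamma values must be non-negative")
  }
  if (is.null(plan_id)) plan_id <- sprintf("P%03d", seq_len(n))
  if (anyDuplicated(plan_id)) stop("plan ids must be unique within a series")
  if (is.null(timestamp)) timestamp <- seq_len(n)
  if (is.unsorted(as.numeric(timestamp))) {
    stop("entries must be in chronological order")
  }
  structure(
    data.frame(plan_id = as.character(plan_id), timestamp = timestamp,
               machine_id = machine_id, metric_name = metric_name,
               value = values, stringsAsFactors = FALSE),
    class = c("qa_series", "data.frame")
  )
}

#' Control-chart constants for the moving-range method
#'
#' Tabulated d2 and d3 for subgroup size n (only n = 2 is tabulated here, the
#' subgroup formed by successive individuals), and the derived coefficients
#' used by the chart-limit formulas: `a = 3 / (d2 * sqrt(n))` (average-chart
#' half-width per unit mean moving range), `b = 1 + 3 d3/d2` (upper
#' range-chart factor) and `b_low = 1 - 3 d3/d2` (its negative lower
#' counterpart, floored to 0 in use).
#'
#' @param n subgroup size; only 2 supported.
#' @return object of class `spc_constants` with fields `n`, `d2`, `d3`, `a`,
#'   `b`, `b_low`.
#' @export
spc_constants <- function(n = 2) {
  if (n != 2) stop("only subgroup size n = 2 is tabulated")
  d2 <- 1.128
  d3 <- 0.853
  structure(
    list(n = n, d2 = d2, d3 = d3,
         a = 3 / (d2 * sqrt(n)),
         b = 1 + 3 * d3 / d2,
         b_low = 1 - 3 * d3 / d2),
    class = "spc_constants"
  )
}

series_values <- function(series) {
  if (inherits(series, "qa_series")) {
    if (length(unique(series$metric_name)) > 1L) {
      stop("series mixes metrics; chart one metric at a time")
    }
    series$value
  } else as.numeric(series)
}

#' Moving ranges of successive QA measurements
#'
#' `R_i = |x_i - x_{i-1}|` for `i = 2..N`. The absolute value makes every
#' range non-negative, as the range-chart formulas require.
#'
#' @param series a `qa_series` or numeric vector with >= 2 entries.
#' @return numeric vector of N-1 moving ranges.
#' @export
moving_ranges <- function(series) {
  x <- series_values(series)
  if (length(x) < 2L) stop("need at least 2 entries for moving ranges")
  abs(diff(x))
}

#' SPC action levels for an individuals / moving-range chart pair
#'
#' Average chart: centre `Ac = mean(x)`, limits `Au/Al = Ac ± a·R̄` with
#' `a = 3/(d2·sqrt(2)) = 1.88`. Range chart: centre `Rc = R̄` (the mean moving
#' range), upper limit `Ru = (1 + 3 d3/d2)·R̄ = 3.267·R̄`, lower limit floored
#' at `Rl = 0` (the raw negative value is kept as a diagnostic). For a metric
#' with a physical upper bound (e.g. 100% pass rate) `Au` is capped and
#' flagged as clipped.
#'
#' @param series a `qa_series` or numeric vector with >= 3 entries.
#' @param constants an [spc_constants()].
#' @param cap_high optional physical upper bound for the metric; `Au` above
#'   it is reported capped.
#' @param baseline optional: use only the first `baseline` entries to
#'   estimate the limits (0 or `NULL` = all entries, the retrospective case).
#' @return object of class `chart_limits` with `Ac`, `Au`, `Al`, `Rc`, `Ru`,
#'   `Rl`, `r_bar`, `au_raw`, `rl_raw`, and clipping flags.
#' @export
chart_limits <- function(series, constants = spc_constants(),
                         cap_high = NULL, baseline = NULL) {
  x <- series_values(series)
  if (!is.null(baseline) && baseline > 0) {
    if (baseline < 3L) stop("baseline must contain at least 3 entries")
    x <- x[seq_len(min(baseline, length(x)))]
  }
  if (length(x) < 3L) stop("need at least 3 entries to estimate limits")
  r <- abs(diff(x))
  r_bar <- mean(r)
  if (r_bar == 0) {
    warning("zero mean moving range: limits degenerate to the centre line")
  }
  ac <- mean(x)
  au_raw <- ac + constants$a * r_bar
  al <- ac - constants$a * r_bar
  au <- au_raw
  au_capped <- FALSE
  if (!is.null(cap_high) && au > cap_high) {
    au <- cap_high
    au_capped <- TRUE
  }
  rl_raw <- constants$b_low * r_bar
  structure(
    list(Ac = ac, Au = au, Al = al,
         Rc = r_bar, Ru = constants$b * r_bar, Rl = 0,
         r_bar = r_bar, au_raw = au_raw, rl_raw = rl_raw,
         au_capped = au_capped, rl_floored = rl_raw < 0,
         constants = constants),
    class = "chart_limits"
  )
}

#' @export
print.chart_limits <- function(x, ...) {
  cat(sprintf(
    "<chart_limits> average: Ac %.4g [Al %.4g, Au %.4g%s]; range: Rc %.4g [0, Ru %.4g]\n",
    x$Ac, x$Al, x$Au, if (x$au_capped) " capped" else "", x$Rc, x$Ru))
  invisible(x)
}

#' Detect out-of-control plans (points outside action levels)
#'
#' Average-chart flags are entries with `x_i < Al` or `x_i > Au`; range-chart
#' flags are moving ranges with `R_i > Ru` (`Rl` is floored at 0 and never
#' flags). In SPC terminology these points are "systematic errors". A flagged
#' moving range involves two successive plans; the flag is attributed to the
#' endpoint whose value lies farther from the average-chart centre, which
#' localises the disturbance on the plan that caused it.
#'
#' @param series a `qa_series` (or numeric vector).
#' @param limits a [chart_limits()], typically fitted on this series or on a
#'   baseline subset of it.
#' @return a list with `average_flags` / `range_flags` (entry indices),
#'   `average_plans` / `range_plans` (plan ids), and `flagged_plans`
#'   (de-duplicated union for this chart pair).
#' @export
detect_out_of_control <- function(series, limits) {
  x <- series_values(series)
  ids <- if (inherits(series, "qa_series")) series$plan_id
         else sprintf("P%03d", seq_along(x))
  avg_idx <- which(x < limits$Al | x > limits$Au)
  r <- abs(diff(x))
  r_idx <- which(r > limits$Ru)      # range i spans entries i and i+1
  r_plans <- integer(0)
  if (length(r_idx)) {
    lo <- r_idx; hi <- r_idx + 1L
    pick_hi <- abs(x[hi] - limits$Ac) >= abs(x[lo] - limits$Ac)
    r_plans <- ifelse(pick_hi, hi, lo)
  }
  list(
    average_flags = avg_idx,
    range_flags = r_idx,
    average_plans = ids[avg_idx],
    range_plans = unique(ids[r_plans]),
    flagged_plans = unique(c(ids[avg_idx], ids[r_plans]))
  )
}

#' Unique plans outside action levels across charts
#'
#' De-duplicates flags across any number of chart fragments (average/range ×
#' metric) and reports per-plan multiplicity: with two metrics charted, a
#' single plan can cause up to four systematic errors (one per chart).
#'
#' @param fragments a list of outputs of [detect_out_of_control()], or a list
#'   of character vectors of flagged plan ids.
#' @return a data frame with `plan_id` and `n_charts` (number of charts in
#'   which the plan is flagged), plus attribute `unique_count`.
#' @export
unique_flagged_plans <- function(fragments) {
  per_chart <- lapply(fragments, function(f) {
    if (is.list(f) && !is.null(f$average_plans)) {
      list(unique(f$average_plans), unique(f$range_plans))
    } else list(unique(as.character(f)))
  })
  per_chart <- unlist(per_chart, recursive = FALSE)
  all_ids <- unlist(per_chart)
  if (!length(all_ids)) {
    out <- data.frame(plan_id = character(0), n_charts = integer(0))
  } else {
    tab <- table(unlist(lapply(per_chart, unique)))
    out <- data.frame(plan_id = names(tab), n_charts = as.integer(tab),
                      row.names = NULL, stringsAsFactors = FALSE)
    out <- out[order(-out$n_charts, out$plan_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "unique_count") <- nrow(out)
  out
}

#' Pearson correlation between two matched QA series
#'
#' Pairs the two series by `plan_id` and returns the Pearson correlation of
#' their metric values (e.g. measurement pass rate vs IDC pass rate).
#'
#' @param series_a,series_b `qa_series` objects sharing >= 3 plan ids.
#' @return Pearson correlation coefficient.
#' @export
correlate_metrics <- function(series_a, series_b) {
  stopifnot(inherits(series_a, "qa_series"), inherits(series_b, "qa_series"))
  m <- merge(series_a[, c("plan_id", "value")],
             series_b[, c("plan_id", "value")], by = "plan_id")
  if (nrow(m) < 3L) stop("need at least 3 matched plan ids")
  if (stats::sd(m$value.x) == 0 || stats::sd(m$value.y) == 0) {
    stop("correlation undefined: a series has zero variance")
  }
  stats::cor(m$value.x, m$value.y)
}
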