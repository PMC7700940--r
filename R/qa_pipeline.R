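#' Pipeline configuration for per-plan QA
#'
#' Fixes the gamma presets and the SPC bookkeeping for a QA process. Both
#' comparison modes use Γ(2%, 1 mm) with global-maximum normalization and a
#' 10% dose cutoff. Plan pass/fail is decided only by the SPC action levels;
#' a static gamma-pass-rate threshold (e.g. the ≥ 90% often quoted for
#' robotic-SRS QA) can be switched on but is off by default.
#'
#' @param mode `"3d-idc"` or `"2d-measurement"`.
#' @param results_csv path of the persistent chronological results CSV.
#' @param static_threshold optional minimum pass rate (percent) for an
#'   additional fixed-threshold verdict; `NULL` (default) disables it.
#' @param log logical; emit one structured JSON log line per plan.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("3d-idc", "2d-measurement"),
                            results_csv = NULL, static_threshold = NULL,
                            log = FALSE) {
  mode <- match.arg(mode)
  structure(
    list(mode = mode, results_csv = results_csv,
         static_threshold = static_threshold, log = log,
         criteria = gamma_criteria(dose_diff_percent = 2, dta_mm = 1,
                                   normalization = "global-max",
                                   cutoff_percent = 10)),
    class = "pipeline_config"
  )
}

results_columns <- c("plan_id", "revision", "timestamp", "machine_id",
                     "comparison_type", "pass_rate", "mean_gamma")

#' Run the QA comparison for one plan and append it to the results record
#'
#' Computes the preset gamma comparison, appends one chronological entry to
#' the persistent results CSV (append-only; re-running a plan id emits a
#' duplicate warning and writes a new revision), and returns the entry with
#' the full gamma result.
#'
#' @param reference,evaluated [dose_grid()] objects for the configured mode.
#' @param config a [pipeline_config()].
#' @param plan_id plan identifier.
#' @param machine_id machine identifier.
#' @param timestamp entry timestamp (default `Sys.time()` formatted).
#' @return list with `entry` (one-row data frame) and `gamma`
#'   (`gamma_result`), invisibly the same when logging.
#' @export
run_plan_qa <- function(reference, evaluated, config, plan_id,
                        machine_id = "CK1", timestamp = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- tryCatch(
    compare_plan(reference, evaluated, mode = config$mode),
    error = function(e) stop("plan ", plan_id, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(timestamp)) timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  revision <- 1L
  existing <- NULL
  if (!is.null(config$results_csv) && file.exists(config$results_csv)) {
    existing <- utils::read.csv(config$results_csv, stringsAsFactors = FALSE)
    dup <- existing$plan_id == plan_id
    if (any(dup)) {
      revision <- max(existing$revision[dup]) + 1L
      warning("plan id '", plan_id, "' already recorded; writing revision ",
              revision)
    }
  }
  entry <- data.frame(
    plan_id = as.character(plan_id), revision = revision,
    timestamp = as.character(timestamp), machine_id = machine_id,
    comparison_type = config$mode,
    pass_rate = res$pass_rate, mean_gamma = res$mean_gamma,
    stringsAsFactors = FALSE
  )
  if (!is.null(config$static_threshold)) {
    entry$static_pass <- res$pass_rate >= config$static_threshold
  }
  if (!is.null(config$results_csv)) {
    utils::write.table(entry, config$results_csv, sep = ",",
                       row.names = FALSE, col.names = is.null(existing),
                       append = !is.null(existing), quote = FALSE)
  }
  if (isTRUE(config$log)) {
    message(jsonlite::toJSON(as.list(entry), auto_unbox = TRUE))
  }
  list(entry = entry, gamma = res)
}

#' Read a persisted QA results CSV as per-metric QA series
#'
#' @param path results CSV written by [run_plan_qa()].
#' @param comparison_type optional filter on the comparison type.
#' @param machine_id optional filter on the machine.
#' @return named list of [qa_series()] (`pass_rate`, `mean_gamma`); only the
#'   latest revision of each plan enters the series.
#' @export
read_qa_results <- function(path, comparison_type = NULL, machine_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(comparison_type)) df <- df[df$comparison_type == comparison_type, ]
  if (!is.null(machine_id)) df <- df[df$machine_id == machine_id, ]
  if (!nrow(df)) stop("no matching entries in ", path)
  keep <- !duplicated(df[, c("plan_id")], fromLast = TRUE)
  df <- df[keep, , drop = FALSE]
  lapply(stats::setNames(c("pass_rate", "mean_gamma"),
                         c("pass_rate", "mean_gamma")), function(m) {
    qa_series(df[[m]], plan_id = df$plan_id, timestamp = seq_len(nrow(df)),
              machine_id = df$machine_id[1L], metric_name = m)
  })
}

#' SPC analysis of a QA process: limits, flags and unique plans
#'
#' Applies [chart_limits()] and [detect_out_of_control()] to each metric of a
#' QA process and aggregates the flagged plans across all charts, the
#' action-level workflow used to commission a QA method. Pass-rate charts
#' have their upper average limit capped at 100%.
#'
#' @param series named list of [qa_series()] (one per metric) for one
#'   machine/process.
#' @param baseline optional number of initial entries used to fit the limits.
#' @return list of class `spc_report` with per-metric `limits` and `flags`,
#'   and `unique_plans` across charts.
#' @export
spc_analysis <- function(series, baseline = NULL) {
  caps <- list(pass_rate = 100)
  limits <- list()
  flags <- list()
  for (m in names(series)) {
    lm <- chart_limits(series[[m]], cap_high = caps[[m]], baseline = baseline)
    limits[[m]] <- lm
    flags[[m]] <- detect_out_of_control(series[[m]], lm)
  }
  structure(
    list(limits = limits, flags = flags,
         unique_plans = unique_flagged_plans(flags)),
    class = "spc_report"
  )
}

#' @export
print.spc_report <- function(x, ...) {
  for (m in names(x$limits)) {
    l <- x$limits[[m]]
    f <- x$flags[[m]]
    cat(sprintf(
      "%s: Ac %.3g [Al %.3g, Au %.3g%s], Rc %.3g, Ru %.3g; %d avg flags, %d range flags\n",
      m, l$Ac, l$Al, l$Au, if (l$au_capped) " capped" else "",
      l$Rc, l$Ru, length(f$average_flags), length(f$range_flags)))
  }
  cat(sprintf("unique plans outside action levels: %d\n",
              attr(x$unique_plans, "unique_count")))
  invisible(x)
}

#' Full commissioning report bundle
#'
#' Combines the beam-model validation sections (output-factor summary and
#' curve pass-rate table), the per-process SPC analyses, and — when two
#' matched comparison types are supplied — the Pearson correlation of their
#' metrics, into one bundle mirroring a commissioning paper's result tables.
#' Missing sections are omitted.
#'
#' @param of_records optional [output_factor_records()].
#' @param comparisons optional list of [validate_curve()] results.
#' @param qa_processes optional named list of processes, each a named list of
#'   [qa_series()] per metric (e.g. `list(meas_ck1 = ..., idc = ...)`).
#' @param correlate optional character vector of two process names to
#'   correlate metric-by-metric.
#' @param out optional path to also write the bundle as JSON.
#' @return list with elements `output_factors`, `curves`, `spc`,
#'   `correlation` (those available).
#' @export
run_commissioning_report <- function(of_records = NULL, comparisons = NULL,
                                     qa_processes = NULL, correlate = NULL,
                                     out = NULL) {
  bundle <- list()
  if (!is.null(of_records)) bundle$output_factors <- of_summary(of_records)
  if (!is.null(comparisons)) {
    bundle$curves <- validation_report(comparisons)$curves
  }
  if (!is.null(qa_processes)) {
    bundle$spc <- lapply(qa_processes, spc_analysis)
    if (!is.null(correlate)) {
      stopifnot(length(correlate) == 2L, all(correlate %in% names(qa_processes)))
      a <- qa_processes[[correlate[1L]]]
      b <- qa_processes[[correlate[2L]]]
      shared <- intersect(names(a), names(b))
      bundle$correlation <- vapply(shared, function(m) {
        correlate_metrics(a[[m]], b[[m]])
      }, numeric(1))
    }
  }
  if (!length(bundle)) stop("no report sections available")
  if (!is.null(out)) {
    jsonlite::write_json(report_to_json(bundle), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  bundle
}

# flatten S3 pieces for JSON serialisation
report_to_json <- function(bundle) {
  out <- bundle
  if (!is.null(out$spc)) {
    out$spc <- lapply(out$spc, function(rep) {
      list(
        limits = lapply(rep$limits, function(l) {
          l[c("Ac", "Au", "Al", "Rc", "Ru", "Rl", "au_capped")]
        }),
        flags = lapply(rep$flags, function(f) {
          f[c("average_plans", "range_plans")]
        }),
        unique_plans = as.data.frame(rep$unique_plans),
        unique_count = attr(rep$unique_plans, "unique_count")
      )
    })
  }
  out
}
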