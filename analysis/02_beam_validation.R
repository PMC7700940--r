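#!/usr/bin/env Rscript
# Step 2: beam-model validation statistics.
#
# Reads the simulated measured/calculated scan sets, compares output factors
# (mean relative error, range, within-1%/within-2% counts per collimator) and
# runs the 1D gamma comparison of every curve pair: depth-dose curves in
# absolute dose with Gamma(2, 0.5), off-centre ratios normalised to the
# central axis with Gamma(1, 0.5) — the build-up region included.
# Outputs: results/table_of_summary.csv, results/table_curve_passrates.csv

library(gammaspc)

meas <- read_scan_csv("scratch/sim/scans_measured.csv")
calc <- read_scan_csv("scratch/sim/scans_calculated.csv")
of_table <- read.csv("scratch/sim/of_table.csv")

ofr <- output_factor_records(of_table$collimator, of_table$field_size_mm,
                             of_table$of_measured, of_table$of_calculated)
of_sum <- of_summary(ofr)
write.csv(of_sum, "results/table_of_summary.csv", row.names = FALSE)
cat("output factors: mean error",
    sprintf("%.2f%% (range %.2f to %.2f), within 1%%: %d/%d, within 2%%: %d/%d\n",
            of_sum$mean_error, of_sum$min_error, of_sum$max_error,
            of_sum$within_1pct, of_sum$n, of_sum$within_2pct, of_sum$n))

key <- function(cv) sprintf("%s|%g|%g", cv$curve_kind, cv$field_size_mm,
                            cv$depth_mm)
calc_by_key <- setNames(calc, vapply(calc, key, ""))

comparisons <- lapply(meas, function(m) {
  cc <- calc_by_key[[key(m)]]
  stopifnot(!is.null(cc))
  cr <- if (m$curve_kind == "DDC") {
    gamma_criteria(2, 0.5, cutoff_percent = 0)
  } else {
    gamma_criteria(1, 0.5, cutoff_percent = 0)
  }
  validate_curve(m, cc, cr)
})

report <- validation_report(comparisons)
write.csv(report$curves, "results/table_curve_passrates.csv", row.names = FALSE)
cat("curve pass rates (mean (min-max) per kind):\n")
print(report$curves[, c("curve_kind", "criteria", "n", "cell")])
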