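#!/usr/bin/env Rscript
# Step 1: simulate the commissioning inputs with known ground truth.
#
# For each MLC field size this writes a "measured" and a "calculated" set of
# water-tank scan curves (a depth-dose curve plus off-centre ratios at five
# depths) and an output-factor table. The calculated set differs from the
# measured one by small, known beam-model errors (penumbra width, attenuation
# and output factor), so downstream validation statistics have a known truth.
# Outputs: scratch/sim/scans_measured.csv, scans_calculated.csv, of_table.csv

library(gammaspc)

set.seed(20260920)
dir.create("scratch/sim", showWarnings = FALSE, recursive = TRUE)

field_sizes <- cyberknife_field_sizes()$mlc
ocr_depths <- c(15, 50, 100, 200, 300)

meas_curves <- list()
calc_curves <- list()
of_rows <- list()

for (fs in field_sizes) {
  meas_spec <- beam_model_spec(fs, noise_sigma_percent = 0.3)
  # known model errors: slightly wider penumbra, slightly off attenuation,
  # and an output-factor error growing toward the smallest fields
  of_err <- 1 + (0.045 * exp(-fs / 12) + runif(1, -0.006, 0.006))
  calc_spec <- beam_model_spec(
    fs,
    penumbra_sigma_mm = 2.5 + runif(1, -0.1, 0.15),
    mu_atten = 0.005 * (1 + runif(1, -0.01, 0.01)),
    of_curve = function(f) of_err * f^2 / (f^2 + 3.5^2))

  depths <- seq(0, 300, by = 1)
  meas_curves <- c(meas_curves, list(gen_ddc(meas_spec, depths, seed = round(fs * 7))))
  calc_curves <- c(calc_curves, list(gen_ddc(calc_spec, depths)))
  for (d in ocr_depths) {
    meas_curves <- c(meas_curves, list(gen_ocr(meas_spec, depth_mm = d,
                                               seed = round(fs * 13 + d))))
    calc_curves <- c(calc_curves, list(gen_ocr(calc_spec, depth_mm = d)))
  }
  of_rows[[length(of_rows) + 1L]] <- data.frame(
    collimator = "mlc", field_size_mm = fs,
    of_measured = meas_spec$of_curve(fs),
    of_calculated = calc_spec$of_curve(fs))
}

write_scan_csv(meas_curves, "scratch/sim/scans_measured.csv")
write_scan_csv(calc_curves, "scratch/sim/scans_calculated.csv")
of_table <- do.call(rbind, of_rows)
write.csv(of_table, "scratch/sim/of_table.csv", row.names = FALSE)

cat(sprintf(
  "simulated %d measured and %d calculated curves over %d field sizes\n",
  length(meas_curves), length(calc_curves), length(field_sizes)))
cat(sprintf("output-factor errors span %.2f%% to %.2f%%\n",
            min(100 * (of_table$of_calculated / of_table$of_measured - 1)),
            max(100 * (of_table$of_calculated / of_table$of_measured - 1))))
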