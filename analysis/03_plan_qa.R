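#!/usr/bin/env Rscript
# Step 3: per-plan QA of a synthetic 84-plan cohort, twice.
#
# Every plan is compared with the clinical presets (Gamma(2%, 1 mm), global
# maximum, 10% cutoff) along both QA routes: a 2D measurement-like plane
# comparison and a 3D independent-calculation-like volume comparison. Most
# plans carry only mild noise, a small residual scale and a sub-voxel setup
# shift; three plans per route carry a localized dose error (a superficial /
# interface-like discrepancy) that the SPC step should later flag.
# Each QA process keeps its own append-only chronological record.
# Outputs: results/qa_results_meas.csv, results/qa_results_idc.csv,
#          results/injected_plans.csv

library(gammaspc)

set.seed(20260921)
dir.create("results", showWarnings = FALSE)

n_plans <- 84
modes <- c(meas = "2d-measurement", idc = "3d-idc")
bad <- list(meas = sort(sample(n_plans, 3)), idc = sort(sample(n_plans, 3)))
cat("injected out-of-control plans: measurement:", bad$meas,
    "| idc:", bad$idc, "\n")

for (proc in names(modes)) {
  mode <- modes[[proc]]
  nd <- if (proc == "meas") 2 else 3
  csv <- sprintf("results/qa_results_%s.csv", proc)
  if (file.exists(csv)) file.remove(csv)
  cfg <- pipeline_config(mode, results_csv = csv)
  for (i in seq_len(n_plans)) {
    pert <- perturbation_spec(
      global_scale_percent = runif(1, -0.5, 0.5),
      shift_mm = runif(nd, -0.3, 0.3),
      gaussian_noise_percent = if (nd == 2) 1 else 0.5,
      blob = if (i %in% bad[[proc]]) {
        list(centre = rep(0, nd), radius_mm = if (nd == 2) 20 else 16,
             amplitude_percent = if (nd == 2) -7 else -8)
      },
      seed = sample.int(2^31 - 2, 1))
    pair <- gen_dose_pair(
      shape = if (nd == 2) c(23, 23) else c(9, 9, 9),
      spacing = if (nd == 2) 3 else 4,
      base_pattern = "single-gaussian-target", perturbation = pert,
      target_sigma_mm = if (nd == 2) 30 else 25)
    run_plan_qa(pair$reference, pair$evaluated, cfg,
                plan_id = sprintf("P%03d", i), machine_id = "CK1",
                timestamp = i)
  }
  res <- read.csv(csv)
  cat(sprintf("%s: mean pass rate %.1f%% (range %.1f-%.1f), mean gamma %.2f\n",
              mode, mean(res$pass_rate), min(res$pass_rate),
              max(res$pass_rate), mean(res$mean_gamma)))
}
inj <- data.frame(process = names(bad),
                  plans = vapply(bad, function(b) {
                    paste(sprintf("P%03d", b), collapse = ";")
                  }, ""))
write.csv(inj, "results/injected_plans.csv", row.names = FALSE)
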