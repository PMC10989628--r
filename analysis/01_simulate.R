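#!/usr/bin/env Rscript
# Step 1: generate the study's synthetic inputs -- a 4-electrode array with
# electrode-to-electrode variation, its 9-step calibration, 12 drifting soil
# extract samples spanning 1e-5..1e-3 M measured both directly and by
# two-spike standard addition, and an 11-sample paired extraction table.

source("analysis/_common.R")

arr <- simulate_array(array_spec(), seed = SEED)
cat("simulated array:\n")
print(arr, digits = 4)

cal <- simulate_calibration(arr, calibration_design(), seed = SEED + 101L)
sam <- simulate_sample_emfs(arr, DRIFT, TRUE_CONC, seed = SEED + 202L)
sa <- simulate_sa_table(arr, default_sa_schedule(), TRUE_CONC, DRIFT,
                        seed = SEED + 303L)
cmp <- simulate_comparison_table(comparison_scenario(), seed = SEED + 404L)

write_ise_csv(cal, file.path(DATA_DIR, "calibration.csv"), "calibration")
write_ise_csv(sam, file.path(DATA_DIR, "samples.csv"), "sample")
write_ise_csv(sa, file.path(DATA_DIR, "standard_addition.csv"), "standard_addition")
write_ise_csv(cmp, file.path(DATA_DIR, "comparison.csv"), "comparison")
utils::write.csv(data.frame(sample_id = sprintf("S%02d", seq_along(TRUE_CONC)),
                            true_conc_M = TRUE_CONC),
                 file.path(DATA_DIR, "true_concentrations.csv"),
                 row.names = FALSE, quote = FALSE)

cat(sprintf("\nwrote %d calibration rows, %d sample readings, %d SA rows, %d comparison rows under %s\n",
            nrow(cal), nrow(sam), nrow(sa), nrow(cmp), DATA_DIR))
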