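# Shared settings for the numbered analysis drivers. Every script can be run
# from the repository root with Rscript; later steps re-read the tables the
# earlier steps wrote under results/data/.

suppressMessages(library(isebayes))

SEED <- 20L
DATA_DIR <- "results/data"
TABLE_DIR <- "results/tables"
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(TABLE_DIR, recursive = TRUE, showWarnings = FALSE)

ANALYTE <- analyte_nh4()
DRIFT <- drift_model("occasion_offset", 10)
TRUE_CONC <- 10^seq(-5, -3, length.out = 12)

fit_from_csv <- function() {
  cal <- read_calibration_csv(file.path(DATA_DIR, "calibration.csv"))
  fit_array(cal, settings = mcmc_settings(seed = SEED), analyte = ANALYTE)
}
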