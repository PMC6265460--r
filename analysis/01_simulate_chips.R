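#!/usr/bin/env Rscript
# Generate the two synthetic single-cell qPCR chips used throughout the
# workflow: a dose-response chip sampled at the +35 min plateau (5 GnRH doses
# x 120 wells) and a time-course chip at 2 nM (4 time points x 120 wells).
# Writes the Biomark-style CSVs plus ground-truth sidecars under results/.

suppressPackageStartupMessages(library(scquantal))
dir.create("results", showWarnings = FALSE)
set.seed(NULL)

params <- quantal_params()
cat("Quantal model defaults: p0 =", params$regulated$p0[1],
    ", pmax =", params$regulated$pmax[1], "\n")
cat("EC50s (nM):", paste(params$regulated$gene, params$regulated$ec50,
                         sep = "=", collapse = ", "), "\n")

dose_design <- condition_design(times = 35, n_cells = 120,
                                qc_failure_rate = 0.05, seed = 101)
dose_chip <- simulate_sc_qpcr(dose_design)
write_ct_csv(dose_chip$ct, "results/chip_dose_response.csv")

time_design <- condition_design(doses = 2, times = c(-1, 25, 35, 60),
                                n_cells = 120, qc_failure_rate = 0.05,
                                seed = 102)
time_chip <- simulate_sc_qpcr(time_design)
write_ct_csv(time_chip$ct, "results/chip_time_course.csv")

# ground-truth sidecars: per-well debris flag and per cell x gene on/off
truth_sidecar <- function(sim, path) {
  on <- sim$truth$on
  df <- data.frame(well_id = rownames(on),
                   debris = as.integer(sim$truth$debris),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(on * 1L))
  utils::write.csv(df, path, row.names = FALSE)
}
truth_sidecar(dose_chip, "results/chip_dose_response.truth.csv")
truth_sidecar(time_chip, "results/chip_time_course.truth.csv")

cat("Dose chip:", nrow(dose_chip$ct$ct), "wells x", ncol(dose_chip$ct$ct),
    "markers;", sum(dose_chip$truth$debris), "debris wells\n")
cat("Time chip:", nrow(time_chip$ct$ct), "wells;",
    sum(time_chip$truth$debris), "debris wells\n")
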