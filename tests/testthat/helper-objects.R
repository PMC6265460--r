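# In-code fixtures: tiny expression/call objects built directly, and a small
# default chip simulation shared across tests.

make_cells <- function(n, dose = 0, time = 35) {
  data.frame(
    well_id = sprintf("W%03d", seq_len(n)),
    dose_nM = rep_len(dose, n),
    time_min = rep_len(time, n),
    treatment = ifelse(rep_len(dose, n) > 0, "GnRH", "vehicle"),
    replicate = "chip1",
    stringsAsFactors = FALSE
  )
}

make_genes <- function(ids, role = "regulated") {
  data.frame(marker_id = ids, role = rep_len(role, length(ids)),
             stringsAsFactors = FALSE)
}

# expression matrix from a plain matrix; columns become regulated genes unless
# roles given
make_expr <- function(m, dose = 0, time = 35, roles = "regulated") {
  if (is.null(colnames(m))) colnames(m) <- sprintf("g%d", seq_len(ncol(m)))
  expression_matrix(m, make_cells(nrow(m), dose, time),
                    make_genes(colnames(m), roles))
}

# call matrix directly from a binary matrix (bypasses policies)
make_calls <- function(calls, dose = 0, time = 35, roles = "regulated") {
  if (is.null(colnames(calls))) colnames(calls) <- sprintf("g%d", seq_len(ncol(calls)))
  cells <- make_cells(nrow(calls), dose, time)
  rownames(calls) <- cells$well_id
  structure(
    list(calls = calls, policy = "detected", cells = cells,
         genes = make_genes(colnames(calls), roles), modality = NULL),
    class = "call_matrix"
  )
}

# one dose-response chip at the +35 min plateau
sim_chip <- function(n_cells = 120, qc_failure_rate = 0, seed = 1,
                     params = quantal_params(), doses = c(0, 0.5, 2, 8, 20)) {
  simulate_sc_qpcr(
    condition_design(doses = doses, times = 35, n_cells = n_cells,
                     qc_failure_rate = qc_failure_rate, seed = seed),
    params
  )
}

IEG <- c("Egr1", "Fos", "Egr2", "Fosb")
HK <- c("Eef1a", "H2fz", "Rps11", "Rps25")
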