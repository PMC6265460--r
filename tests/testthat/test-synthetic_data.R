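# Ground-truth generators: quantal chip, cell-cycle counts, bulk profiles.

test_that("parameter and design invariants are enforced", {
  expect_error(condition_design(doses = c(-1, 2)), "non-negative")
  expect_error(condition_design(n_cells = 0), "n_cells")
  expect_error(condition_design(qc_failure_rate = 1.5), "qc_failure_rate")
  reg <- quantal_params()$regulated
  reg$p0 <- 0.5; reg$pmax <- 0.2
  expect_error(quantal_params(regulated = reg), "p0 <= pmax")
  reg <- quantal_params()$regulated
  reg$ec50[1] <- -2
  expect_error(quantal_params(regulated = reg), "positive")
})

test_that("study-design defaults match the pulse paradigm", {
  d <- condition_design()
  expect_identical(d$doses, c(0, 0.5, 2, 8, 20))
  expect_identical(d$times, c(-1, 25, 35, 60))
  expect_identical(d$pulses, 4)
  expect_identical(d$pulse_interval_h, 2)
  expect_identical(d$pulse_min, 5)
})

test_that("generated panel always contains 54 genes, 3+8 spikes, 5 DNA markers", {
  sim <- sim_chip(n_cells = 3, seed = 2)
  cls <- table(sim$ct$markers$class)
  expect_identical(as.integer(cls[c("gene", "fluidigm_spike", "ercc_spike", "dna_marker")]),
                   c(54L, 3L, 8L, 5L))
  expect_identical(ncol(sim$ct$ct), 70L)  # 54 + 3 + 8 + 5
})

test_that("zero activation probability silences regulated genes only", {
  reg <- quantal_params()$regulated
  reg$p0 <- 0; reg$pmax <- 0
  sim <- sim_chip(n_cells = 10, seed = 5, params = quantal_params(regulated = reg))
  e <- ct_to_expression(sim$ct)
  expect_true(all(e$expr[, IEG] == 0))
  expect_true(all(e$expr[, HK] > 0))
})

test_that("identical seed and parameters give identical output elementwise", {
  d <- condition_design(times = 35, n_cells = 40, qc_failure_rate = 0.1, seed = 9)
  a <- simulate_sc_qpcr(d)
  b <- simulate_sc_qpcr(d)
  expect_identical(a$ct$ct, b$ct$ct)
  expect_identical(a$truth$on, b$truth$on)
  expect_identical(a$truth$debris, b$truth$debris)
  expect_gt(sum(a$truth$debris), 0)
})

test_that("activation probability is non-decreasing in dose at every time", {
  p <- quantal_params()
  grid <- c(0, 0.1, 0.5, 1, 2, 4, 8, 16, 20, 50)
  for (g in IEG) {
    for (t in c(-1, 25, 35, 60)) {
      expect_true(all(diff(activation_prob(p, g, grid, t)) >= -1e-12))
    }
  }
  # pre-pulse time point carries only basal activation
  expect_equal(activation_prob(p, "Fos", 20, -1), p$regulated$p0[p$regulated$gene == "Fos"])
})

test_that("on-level distribution is dose-independent by construction", {
  sim <- sim_chip(n_cells = 400, seed = 21)
  e <- ct_to_expression(sim$ct)
  on <- sim$truth$on
  # two-sample location test between on-cells at 2 nM and 20 nM
  for (g in c("Egr1", "Fosb")) {
    lo <- e$expr[e$cells$dose_nM == 2 & on[, g], g]
    hi <- e$expr[e$cells$dose_nM == 20 & on[, g], g]
    expect_gt(stats::t.test(lo, hi)$p.value, 0.01)
  }
})

test_that("debris wells lack every marker including spikes", {
  sim <- sim_chip(n_cells = 100, qc_failure_rate = 0.2, seed = 7)
  dbr <- sim$truth$debris
  expect_true(all(is.na(sim$ct$ct[dbr, ])))
  expect_true(all(!is.na(sim$ct$ct[!dbr, "FlSpike1"])))
})

test_that("leaky off option adds weak signal without changing truth labels", {
  p_leak <- quantal_params(leak_prob = 0.5, leak_mean = 3, leak_sd = 0.5)
  sim <- simulate_sc_qpcr(condition_design(doses = 0, times = 35, n_cells = 200,
                                           qc_failure_rate = 0, seed = 8), p_leak)
  e <- ct_to_expression(sim$ct)
  off_expr <- e$expr[, "Fosb"][!sim$truth$on[, "Fosb"]]
  expect_gt(mean(off_expr > 0), 0.3)   # leak detected in off cells
  expect_lt(max(off_expr), 8)          # but at low level
})

test_that("cell-cycle generator: infinite fold confines counts to own-phase genes", {
  cc <- simulate_cellcycle_counts(50, depth = 500, fold = Inf,
                                  n_background = 20, seed = 3)
  for (i in seq_len(10)) {
    own <- cc$gene_sets[[cc$phase[i]]]
    expect_true(all(cc$counts[i, setdiff(colnames(cc$counts), own)] == 0))
  }
})

test_that("cell-cycle generator: fold 1 carries no phase signal", {
  cc <- simulate_cellcycle_counts(400, depth = 1000, fold = 1, seed = 4)
  sc <- score_phases(cc$counts, cc$gene_sets)
  acc <- mean(sc$phase == cc$phase)
  # accuracy about 1/n_phases (0.2); allow generous Monte-Carlo slack
  expect_lt(acc, 0.30)
})

test_that("cell-cycle generator rejects bad inputs", {
  expect_error(simulate_cellcycle_counts(10, gene_sets = list(a = character(), b = "g1")),
               "empty")
  expect_error(simulate_cellcycle_counts(10, gene_sets = list(a = "g1")), "2 phases")
  expect_error(simulate_cellcycle_counts(10, depth = 0), "depth")
})

test_that("bulk profile generator hits the requested log-scale correlation", {
  # perfect correlation, zero noise: identical samples
  m1 <- simulate_bulk_profiles(500, 3, within_group_corr = 1, seed = 5)
  r1 <- pairwise_pearson(log_cpm(m1))$cor
  expect_equal(max(abs(r1[upper.tri(r1)] - 1)), 0, tolerance = 1e-12)
  # independence: near-zero off-diagonals at large n_genes
  m0 <- simulate_bulk_profiles(5000, 3, within_group_corr = 0, seed = 6)
  r0 <- pairwise_pearson(log_cpm(m0))$cor
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.05)
  expect_error(simulate_bulk_profiles(1, 2, 0.5), "n_genes")
  expect_error(simulate_bulk_profiles(10, 2, 1.5), "within_group_corr")
})
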