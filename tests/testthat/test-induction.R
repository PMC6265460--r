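# Induction summaries, level-invariance ANOVA, time contrasts, overlaps.

test_that("summary statistics follow the binomial identities", {
  calls <- make_calls(cbind(g = rep(c(1L, 0L), 50)))
  e <- make_expr(cbind(g = rep(c(15, 0), 50)))
  s <- summarize_induction(calls, e, genes = "g")
  expect_identical(s$n_cells, 100L)
  expect_identical(s$n_expressing, 50L)
  expect_identical(s$p_hat, 0.5)
  expect_identical(s$binom_sd, sqrt(0.25 / 100))
  expect_identical(s$induced_mean, 15)
  # count-scale option
  s2 <- summarize_induction(calls, e, genes = "g", sd_scale = "count")
  expect_identical(s2$binom_sd, sqrt(100 * 0.25))
})

test_that("a condition with no expressing cells has absent induced level", {
  calls <- make_calls(cbind(g = rep(0L, 10)))
  e <- make_expr(cbind(g = rep(0, 10)))
  s <- summarize_induction(calls, e, genes = "g")
  expect_identical(s$p_hat, 0)
  expect_identical(s$binom_sd, 0)
  expect_true(is.na(s$induced_mean))
  expect_true(is.na(s$induced_sd))
})

test_that("p_hat tracks the generating probability within binomial noise", {
  # Monte-Carlo oracle: p_true = 0.3, n = 200 cells per replicate
  set.seed(23)
  hits <- 0; reps <- 400
  for (r in seq_len(reps)) {
    on <- (runif(200) < 0.3) * 1L
    calls <- make_calls(cbind(g = on))
    e <- make_expr(cbind(g = on * 15))
    s <- summarize_induction(calls, e, genes = "g")
    if (abs(s$p_hat - 0.3) <= 3 * sqrt(0.3 * 0.7 / 200)) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.99)
})

test_that("binomial SD vanishes as n grows at fixed p_hat", {
  sds <- vapply(c(10, 100, 1000, 10000), function(n) {
    calls <- make_calls(cbind(g = rep(c(1L, 0L), n / 2)))
    e <- make_expr(cbind(g = rep(c(15, 0), n / 2)))
    summarize_induction(calls, e, genes = "g")$binom_sd
  }, 0)
  expect_true(all(diff(sds) < 0))
  expect_lt(sds[4], 0.006)
})

test_that("level invariance: identical groups give F = 0, p = 1", {
  m <- cbind(g = c(1, 2, 3, 1, 2, 3))
  e <- make_expr(m, dose = rep(c(0, 2), each = 3))
  calls <- make_calls(cbind(g = rep(1L, 6)), dose = rep(c(0, 2), each = 3))
  out <- test_level_invariance(e, calls, "g", min_cells = 2)
  expect_true(out$performed)
  expect_equal(out$F, 0)
  expect_equal(out$p_value, 1)
})

test_that("level invariance attains roughly nominal type-I error", {
  set.seed(24)
  rej <- 0; reps <- 300
  for (r in seq_len(reps)) {
    doses <- rep(c(0.5, 2, 8, 20), each = 30)
    v <- rnorm(120, 15, 1)
    e <- make_expr(cbind(g = v), dose = doses)
    calls <- make_calls(cbind(g = rep(1L, 120)), dose = doses)
    if (test_level_invariance(e, calls, "g")$p_value < 0.05) rej <- rej + 1
  }
  expect_gt(rej / reps, 0.02)
  expect_lt(rej / reps, 0.09)
})

test_that("level invariance detects a dose-dependent on-level", {
  set.seed(25)
  doses <- rep(c(2, 20), each = 50)
  v <- c(rnorm(50, 15, 1), rnorm(50, 18, 1))
  e <- make_expr(cbind(g = v), dose = doses)
  calls <- make_calls(cbind(g = rep(1L, 100)), dose = doses)
  expect_lt(test_level_invariance(e, calls, "g")$p_value, 0.001)
})

test_that("groups below the expressing-cell floor are dropped and reported", {
  doses <- rep(c(0, 2, 20), each = 10)
  on <- c(rep(0L, 9), 1L, rep(1L, 20))       # dose 0 has a single expressing cell
  e <- make_expr(cbind(g = ifelse(on == 1, rnorm(30, 15), 0)), dose = doses)
  calls <- make_calls(cbind(g = on), dose = doses)
  out <- test_level_invariance(e, calls, "g", min_cells = 2)
  expect_true(out$performed)
  expect_identical(out$dropped, 0)
  # with only one eligible group the test is flagged, not an error
  out2 <- test_level_invariance(e, calls, "g", doses = c(0, 2), min_cells = 2)
  expect_false(out2$performed)
  expect_true(is.na(out2$p_value))
})

test_that("time-point contrasts agree with the exact-test oracle", {
  s <- rbind(
    data.frame(gene = "g", dose_nM = 2, time_min = -1, n_cells = 100L,
               n_expressing = 5L, p_hat = 0.05, binom_sd = 0.02,
               induced_mean = 15, induced_sd = 1),
    data.frame(gene = "g", dose_nM = 2, time_min = 25, n_cells = 100L,
               n_expressing = 60L, p_hat = 0.6, binom_sd = 0.05,
               induced_mean = 15, induced_sd = 1)
  )
  out <- compare_timepoints(s, "g", baseline_timepoint = -1)
  oracle <- stats::fisher.test(matrix(c(60, 40, 5, 95), 2))$p.value
  expect_equal(out$p_value, oracle)
  expect_true(out$significant)
  # identical proportions: p = 1, not significant
  s$n_expressing <- c(5L, 5L); s$p_hat <- 0.05
  out2 <- compare_timepoints(s, "g", baseline_timepoint = -1)
  expect_equal(out2$p_value, 1)
  expect_false(out2$significant)
  # degenerate identical zeros
  s$n_expressing <- c(0L, 0L); s$n_cells <- c(50L, 50L)
  out3 <- compare_timepoints(s, "g", baseline_timepoint = -1)
  expect_equal(out3$p_value, 1)
})

test_that("time contrasts flag the plateau on simulated pulse data", {
  sim <- simulate_sc_qpcr(condition_design(doses = 2, times = c(-1, 25, 35, 60),
                                           n_cells = 100, qc_failure_rate = 0,
                                           seed = 26))
  e <- ct_to_expression(sim$ct)
  calls <- call_expressing(e)
  s <- summarize_induction(calls, e)
  out <- compare_timepoints(s, "Egr1", baseline_timepoint = -1, dose = 2)
  expect_true(all(out$significant[out$time_min %in% c(25, 35)]))
})

test_that("overlap counts match brute-force enumeration and conserve cells", {
  calls6 <- make_calls(rbind(
    c(1L, 1L, 0L, 0L),
    c(1L, 1L, 1L, 1L),
    c(0L, 0L, 0L, 0L),
    c(1L, 0L, 0L, 0L),
    c(1L, 1L, 0L, 0L),
    c(0L, 0L, 1L, 0L)
  ))
  genes <- colnames(calls6$calls)
  out <- coinduction_overlap(calls6, genes)
  expect_identical(sum(out$n_cells), 6L)
  # independent brute-force oracle over the 16 membership patterns
  for (i in seq_len(nrow(out))) {
    want <- unlist(out[i, genes])
    brute <- sum(apply(calls6$calls == 1, 1, function(r) all(r == want)))
    expect_identical(out$n_cells[i], as.integer(brute))
  }
})

test_that("overlap boundary cases and input validation", {
  none <- make_calls(matrix(0L, 5, 4))
  out <- coinduction_overlap(none, colnames(none$calls))
  expect_identical(out$n_cells[out$region == "none"], 5L)
  expect_identical(sum(out$n_cells), 5L)
  all4 <- make_calls(matrix(1L, 7, 4))
  out2 <- coinduction_overlap(all4, colnames(all4$calls))
  full <- out2$region == paste(colnames(all4$calls), collapse = "+")
  expect_identical(out2$n_cells[full], 7L)
  expect_identical(sum(out2$n_cells[!full]), 0L)
  expect_error(coinduction_overlap(all4, c("g1", "g1")), "duplicate")
  expect_error(coinduction_overlap(all4, "g1"), "between 2 and 6")
})

test_that("expressing fractions rise with dose on generator output", {
  set.seed(27)
  ok <- 0; reps <- 20
  for (r in seq_len(reps)) {
    sim <- sim_chip(n_cells = 120, seed = 300 + r)
    e <- ct_to_expression(sim$ct)
    calls <- call_expressing(e)
    s <- summarize_induction(calls, e)
    rho <- vapply(IEG, function(g) {
      sg <- s[s$gene == g, ]
      suppressWarnings(cor(sg$dose_nM, sg$p_hat, method = "spearman"))
    }, 0)
    if (all(rho > 0)) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.95)
})
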