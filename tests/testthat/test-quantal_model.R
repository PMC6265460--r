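# Per-dose estimates, Hill-constrained fits, sensitivity ranking, dispersion
# diagnostics.

hill_p <- function(d, p0, pmax, ec50, h) {
  p0 + (pmax - p0) * ifelse(d == 0, 0, d^h / (ec50^h + d^h))
}
DOSES <- c(0, 0.5, 2, 8, 20)

test_that("per-dose estimates are binomial MLEs with exact intervals", {
  out <- fit_per_dose(c(9, 0), c(10, 10), doses = c(1, 2))
  expect_identical(out$p_hat, c(0.9, 0))
  expect_equal(out$lower[2], 0)
  expect_equal(out$lower[1], stats::binom.test(9, 10)$conf.int[1])
  # a dose with no cells is flagged absent
  out2 <- fit_per_dose(c(0, 3), c(0, 10), doses = c(1, 2))
  expect_true(is.na(out2$p_hat[1]))
  expect_error(fit_per_dose(c(5), c(3)), "k <= n")
})

test_that("exact intervals reach nominal coverage", {
  set.seed(31)
  covered <- 0; reps <- 2000
  ks <- rbinom(reps, 50, 0.3)
  for (k in ks) {
    ci <- stats::binom.test(k, 50)$conf.int
    if (ci[1] <= 0.3 && 0.3 <= ci[2]) covered <- covered + 1
  }
  out <- fit_per_dose(ks[1], 50)
  expect_equal(c(out$lower, out$upper),
               as.vector(stats::binom.test(ks[1], 50)$conf.int))
  expect_gte(covered / reps, 0.95)
})

test_that("flat data are reported as flat with EC50 undefined", {
  f <- fit_hill(DOSES, k = rep(30, 5), n = rep(100, 5))
  expect_identical(f$status, "flat")
  expect_true(is.na(f$ec50))
  # all-zero and all-n counts are degenerate, never an exception
  expect_identical(fit_hill(DOSES, rep(0, 5), rep(100, 5))$status, "degenerate")
  expect_identical(fit_hill(DOSES, rep(100, 5), rep(100, 5))$status, "degenerate")
})

test_that("input contracts: distinct doses, low anchor, count bounds", {
  expect_error(fit_hill(c(0, 0, 1), c(1, 1, 1), c(10, 10, 10)), "3 distinct")
  expect_error(fit_hill(c(5, 10, 20), c(1, 2, 3), c(10, 10, 10)), "anchor")
  expect_error(fit_hill(DOSES, c(11, 1, 1, 1, 1), rep(10, 5)), "k <= n")
})

test_that("EC50 is recovered from simulated quantal data", {
  set.seed(32)
  hits <- 0; reps <- 25
  p <- hill_p(DOSES, 0.05, 0.95, 2, 2)
  for (r in seq_len(reps)) {
    k <- rbinom(5, 500, p)
    f <- fit_hill(DOSES, k, rep(500, 5))
    if (f$status == "ok" && abs(f$ec50 - 2) / 2 <= 0.25) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("fitted curve is monotone and bounded by p0 and pmax", {
  set.seed(33)
  k <- rbinom(5, 300, hill_p(DOSES, 0.1, 0.9, 3, 1.5))
  f <- fit_hill(DOSES, k, rep(300, 5))
  grid <- seq(0, 50, length.out = 400)
  curve <- hill_p(grid, f$p0, f$pmax, f$ec50, f$h)
  expect_true(all(diff(curve) >= -1e-12))
  expect_true(all(curve >= f$p0 - 1e-12 & curve <= f$pmax + 1e-12))
})

test_that("maximized likelihood beats the generating parameters (MLE property)", {
  set.seed(34)
  for (r in 1:10) {
    truth <- list(p0 = 0.05, pmax = 0.9, ec50 = runif(1, 1, 6), h = runif(1, 1, 3))
    p <- hill_p(DOSES, truth$p0, truth$pmax, truth$ec50, truth$h)
    k <- rbinom(5, 200, p)
    f <- fit_hill(DOSES, k, rep(200, 5), flat_alpha = 1e-9)
    ll_truth <- sum(k * log(pmax(p, 1e-12)) +
                    (200 - k) * log(pmax(1 - p, 1e-12)))
    expect_gte(f$loglik, ll_truth - 1e-6)
  }
})

test_that("scaling doses and EC50 together leaves the likelihood unchanged", {
  set.seed(35)
  k <- rbinom(5, 400, hill_p(DOSES, 0.05, 0.95, 2, 2))
  f1 <- fit_hill(DOSES, k, rep(400, 5))
  f2 <- fit_hill(DOSES * 10, k, rep(400, 5))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f2$ec50 / f1$ec50, 10, tolerance = 1e-3)
})

test_that("profile-likelihood interval covers the estimate and orders bounds", {
  set.seed(36)
  k <- rbinom(5, 500, hill_p(DOSES, 0.05, 0.95, 2, 2))
  f <- fit_hill(DOSES, k, rep(500, 5))
  ci <- profile_ci_ec50(f)
  expect_true(ci[1] < f$ec50 && f$ec50 < ci[2])
  expect_true(all(ci > 0))
})

test_that("sensitivity ranking orders by EC50 with CI-based confidence", {
  set.seed(37)
  n <- rep(500, 5)
  fits <- list(
    fast = fit_hill(DOSES, rbinom(5, 500, hill_p(DOSES, 0.05, 0.95, 1, 2)), n),
    slow = fit_hill(DOSES, rbinom(5, 500, hill_p(DOSES, 0.05, 0.95, 10, 2)), n)
  )
  out <- rank_sensitivity(fits, confidence = "profile")
  expect_identical(out$ranking$gene, c("fast", "slow"))
  expect_identical(out$pairs$confidence, "high")
  # single usable gene: ranking of length 1, flagged, no pairs
  one <- rank_sensitivity(fits["fast"], confidence = "none")
  expect_identical(nrow(one$ranking), 1L)
  expect_null(one$pairs)
  # flat fits are excluded
  fits$flat <- fit_hill(DOSES, rep(100, 5), rep(300, 5))
  out2 <- rank_sensitivity(fits, confidence = "none")
  expect_identical(out2$excluded, "flat")
})

test_that("dispersion check is skipped for unusable fits and tiny samples", {
  flat <- fit_hill(DOSES, rep(30, 5), rep(100, 5))
  out <- posterior_predictive_check(flat)
  expect_false(out$performed)
  set.seed(38)
  k <- rbinom(5, 1, hill_p(DOSES, 0.05, 0.95, 2, 2))
  tiny <- suppressWarnings(fit_hill(DOSES, k, rep(1, 5)))
  out2 <- posterior_predictive_check(tiny)
  expect_false(out2$performed)
})

test_that("dispersion check: calibrated on binomial data, powered on beta-binomial", {
  set.seed(39)
  p <- hill_p(DOSES, 0.05, 0.95, 2, 2)
  tails <- c()
  while (length(tails) < 15) {
    k <- rbinom(5, 500, p)
    f <- fit_hill(DOSES, k, rep(500, 5))
    if (f$status != "ok") next
    tails <- c(tails, posterior_predictive_check(f, B = 40)$tail_prob)
  }
  # tail probabilities spread over the unit interval, not piled at 0
  expect_gt(mean(tails), 0.2)
  expect_lt(mean(tails < 0.05), 0.3)
  # shared per-dose beta draws (rho = 0.2) inflate the deviance
  rho <- 0.2
  a <- p * (1 / rho - 1); b <- (1 - p) * (1 / rho - 1)
  hits <- 0; usable <- 0
  while (usable < 12) {
    kb <- rbinom(5, 500, rbeta(5, a, b))
    fb <- fit_hill(DOSES, kb, rep(500, 5))
    if (fb$status != "ok") next
    usable <- usable + 1
    if (posterior_predictive_check(fb, B = 40)$tail_prob < 0.05) hits <- hits + 1
  }
  expect_gte(hits / usable, 0.6)
})
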