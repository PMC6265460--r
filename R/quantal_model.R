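# Quantal activation model fitting.
#
# The observable per gene and dose c is k expressing cells out of n; under the
# quantal model k ~ Binomial(n, p(c)). The assumption-free estimate is the
# per-dose MLE with an exact interval; the Hill-constrained fit
# p(c) = p0 + (pmax - p0) * c^h / (ec50^h + c^h) summarizes the monotone dose
# dependence with an interpretable EC50 used to rank gene sensitivity.

#' Per-dose activation probability estimates with exact intervals
#'
#' Maximum-likelihood estimate `k / n` per dose with a Clopper-Pearson
#' interval (via [stats::binom.test()]). Doses with `n = 0` are flagged
#' absent.
#'
#' @param k expressing-cell counts per dose.
#' @param n total cells per dose.
#' @param doses optional dose labels (nM).
#' @param conf_level interval coverage (default 0.95).
#' @return data.frame: dose_nM, k, n, p_hat, lower, upper.
#' @export
fit_per_dose <- function(k, n, doses = seq_along(k), conf_level = 0.95) {
  if (length(k) != length(n) || length(k) != length(doses)) {
    stop("k, n and doses must have equal length")
  }
  if (any(k < 0) || any(k > n)) stop("counts must satisfy 0 <= k <= n")
  if (length(k) < 1) stop("need at least one dose")
  rows <- lapply(seq_along(k), function(i) {
    if (n[i] == 0) {
      return(data.frame(dose_nM = doses[i], k = 0L, n = 0L,
                        p_hat = NA_real_, lower = NA_real_, upper = NA_real_))
    }
    bt <- stats::binom.test(k[i], n[i], conf.level = conf_level)
    data.frame(dose_nM = doses[i], k = k[i], n = n[i], p_hat = k[i] / n[i],
               lower = bt$conf.int[1], upper = bt$conf.int[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Hill curve on the probability scale; p(0) = p0 exactly. The occupancy
# fraction is computed as 1 / (1 + (ec50/dose)^h), which stays finite for any
# positive ec50 and h (overflow of the ratio power saturates to 0 or 1).
hill_prob <- function(dose, p0, pmax, ec50, h) {
  frac <- ifelse(dose == 0, 0, 1 / (1 + (ec50 / dose)^h))
  p0 + (pmax - p0) * frac
}

# analytic gradient of the negative binomial log-likelihood in the
# unconstrained parameterization (theta = a, b, log ec50, log h)
.hill_nll_grad <- function(theta, doses, k, n) {
  pmax_ <- stats::plogis(theta[1])
  rho <- stats::plogis(theta[2])
  ec <- exp(theta[3]); h <- exp(theta[4])
  f <- ifelse(doses == 0, 0, 1 / (1 + (ec / doses)^h))
  p <- pmax_ * (rho + (1 - rho) * f)
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  w <- k / pc - (n - k) / (1 - pc)
  w[p != pc] <- 0
  dp_da <- (rho + (1 - rho) * f) * pmax_ * (1 - pmax_)
  dp_db <- pmax_ * (1 - f) * rho * (1 - rho)
  amp <- pmax_ * (1 - rho)           # pmax - p0
  dp_dc <- -amp * h * f * (1 - f)
  dp_dd <- ifelse(doses == 0, 0,
                  amp * f * (1 - f) * log(ifelse(doses == 0, 1, doses) / ec) * h)
  -c(sum(w * dp_da), sum(w * dp_db), sum(w * dp_dc), sum(w * dp_dd))
}

# binomial log-likelihood at probabilities p (clamped away from 0/1)
.binom_ll <- function(k, n, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(k * log(p) + (n - k) * log(1 - p))
}

# unconstrained parameterization: pmax = plogis(a); p0 = pmax * plogis(b);
# ec50 = exp(c); h = exp(d). Guarantees 0 <= p0 <= pmax <= 1, ec50 > 0, h > 0.
.theta_to_par <- function(theta) {
  pmax <- stats::plogis(theta[1])
  list(p0 = pmax * stats::plogis(theta[2]), pmax = pmax,
       ec50 = exp(theta[3]), h = exp(theta[4]))
}

.par_to_theta <- function(p0, pmax, ec50, h) {
  pmax <- min(max(pmax, 1e-4), 1 - 1e-4)
  ratio <- min(max(p0 / pmax, 1e-4), 1 - 1e-4)
  c(stats::qlogis(pmax), stats::qlogis(ratio), log(ec50), log(h))
}

#' Fit the Hill-constrained binomial dose-response
#'
#' Maximizes the binomial log-likelihood over `(p0, pmax, ec50, h)` subject to
#' `0 <= p0 <= pmax <= 1`, `ec50 > 0`, `h > 0`, via a smooth reparameterization
#' and deterministic multi-start quasi-Newton optimization (EC50 starts on a
#' log-spaced grid across the dose range; ties broken by highest likelihood,
#' then smallest EC50). Data with no dose trend — likelihood-ratio test
#' against the constant-probability model not significant at `flat_alpha` —
#' are reported as `flat` with EC50 undefined; all-zero or all-n counts are
#' `degenerate`. Dose 0 is handled exactly (`p(0) = p0`); doses are never
#' log-transformed.
#'
#' @param doses dose levels (nM); at least 3 distinct values including a
#'   zero/low anchor (minimum dose 0 or below a tenth of the maximum).
#' @param k expressing counts per dose.
#' @param n total cells per dose.
#' @param fix_h optional fixed Hill coefficient (NULL = free).
#' @param n_starts number of EC50 grid starts (>= 8 recommended).
#' @param flat_alpha level of the likelihood-ratio flatness screen.
#' @return object of class `hill_fit`: parameter estimates, log-likelihoods
#'   (fit, constant, saturated), deviance, convergence flag, `status` in
#'   ok/flat/degenerate, and the per-dose table from [fit_per_dose()].
#' @export
fit_hill <- function(doses, k, n, fix_h = NULL, n_starts = 8,
                     flat_alpha = 0.05) {
  if (length(unique(doses)) < 3) stop("need at least 3 distinct doses")
  if (any(k < 0) || any(k > n)) stop("counts must satisfy 0 <= k <= n")
  if (min(doses) > 0 && min(doses) > max(doses) / 10) {
    stop("dose series lacks a zero/low anchor")
  }
  per_dose <- fit_per_dose(k, n, doses)
  p_const <- sum(k) / sum(n)
  ll_const <- .binom_ll(k, n, rep(p_const, length(k)))
  ll_sat <- .binom_ll(k, n, ifelse(n > 0, k / n, 0))

  out <- structure(
    list(doses = doses, k = k, n = n, per_dose = per_dose,
         p0 = NA_real_, pmax = NA_real_, ec50 = NA_real_, h = NA_real_,
         loglik = NA_real_, loglik_const = ll_const, loglik_sat = ll_sat,
         deviance = NA_real_, converged = FALSE, status = "degenerate",
         lrt_p = NA_real_, ec50_ci = c(NA_real_, NA_real_)),
    class = "hill_fit"
  )
  if (sum(k) == 0 || sum(k) == sum(n)) return(out)

  nll <- function(theta) {
    par <- .theta_to_par(if (is.null(fix_h)) theta else c(theta, log(fix_h)))
    -.binom_ll(k, n, hill_prob(doses, par$p0, par$pmax, par$ec50, par$h))
  }
  ngr <- function(theta) {
    g <- .hill_nll_grad(if (is.null(fix_h)) theta else c(theta, log(fix_h)),
                        doses, k, n)
    if (is.null(fix_h)) g else g[1:3]
  }
  pos <- doses[doses > 0]
  ec_grid <- exp(seq(log(min(pos) / 4), log(max(pos) * 4),
                     length.out = n_starts))
  p_lo <- max(min(per_dose$p_hat[which.min(doses)], 0.9), 0.01)
  p_hi <- max(per_dose$p_hat[which.max(doses)], p_lo + 0.01)
  best <- NULL
  for (ec in ec_grid) {
    for (h0 in c(1, 2)) {
      th <- .par_to_theta(p_lo, p_hi, ec, h0)
      if (!is.null(fix_h)) th <- th[1:3]
      opt <- tryCatch(
        stats::optim(th, nll, gr = ngr, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) NULL
      )
      if (is.null(opt)) next
      cand <- list(opt = opt, ec50 = .theta_to_par(
        if (is.null(fix_h)) opt$par else c(opt$par, log(fix_h)))$ec50)
      if (is.null(best) || opt$value < best$opt$value - 1e-9 ||
          (abs(opt$value - best$opt$value) <= 1e-9 && cand$ec50 < best$ec50)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(out)
  par <- .theta_to_par(if (is.null(fix_h)) best$opt$par
                       else c(best$opt$par, log(fix_h)))
  ll <- -best$opt$value
  df_extra <- if (is.null(fix_h)) 3 else 2
  lrt_p <- stats::pchisq(2 * (ll - ll_const), df = df_extra,
                         lower.tail = FALSE)
  out$p0 <- par$p0; out$pmax <- par$pmax; out$ec50 <- par$ec50; out$h <- par$h
  out$loglik <- ll
  out$deviance <- 2 * (ll_sat - ll)
  out$converged <- best$opt$convergence == 0
  out$lrt_p <- lrt_p
  out$status <- if (lrt_p >= flat_alpha) "flat" else "ok"
  if (out$status == "flat") {
    out$ec50 <- NA_real_
  }
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("hill_fit [%s]: p0=%.3f pmax=%.3f ec50=%.3g nM h=%.2f  (logLik %.2f, deviance %.2f)\n",
              x$status, x$p0, x$pmax, x$ec50, x$h, x$loglik, x$deviance))
  invisible(x)
}

#' Profile-likelihood confidence interval for the EC50
#'
#' Profiles the binomial log-likelihood over a log-EC50 grid (re-optimizing
#' the remaining parameters at each point) and inverts the likelihood-ratio
#' statistic at the chi-squared(1) quantile, interpolating the crossings.
#'
#' @param fit a converged `hill_fit` with status `ok`.
#' @param level interval coverage (default 0.95).
#' @param span half-width of the profiling grid in log-units around the
#'   estimate.
#' @param n_grid grid points per side.
#' @return numeric `c(lower, upper)` in dose units; a side that never crosses
#'   the threshold inside the grid is reported as the grid edge.
#' @export
profile_ci_ec50 <- function(fit, level = 0.95, span = log(64), n_grid = 25) {
  stopifnot(inherits(fit, "hill_fit"))
  if (fit$status != "ok" || !fit$converged) {
    return(c(NA_real_, NA_real_))
  }
  doses <- fit$doses; k <- fit$k; n <- fit$n
  cut <- stats::qchisq(level, df = 1) / 2
  prof_ll <- function(log_ec) {
    nll3 <- function(th) {
      par <- .theta_to_par(c(th[1], th[2], log_ec, th[3]))
      v <- -.binom_ll(k, n, hill_prob(doses, par$p0, par$pmax, par$ec50, par$h))
      if (!is.finite(v)) 1e10 else v
    }
    gr3 <- function(th) {
      .hill_nll_grad(c(th[1], th[2], log_ec, th[3]), doses, k, n)[c(1, 2, 4)]
    }
    th0 <- .par_to_theta(fit$p0, fit$pmax, 1, fit$h)[c(1, 2, 4)]
    opt <- stats::optim(th0, nll3, gr = gr3, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-10))
    -opt$value
  }
  bound <- function(dir) {
    grid <- fit$ec50 * exp(dir * seq(0, span, length.out = n_grid + 1))[-1]
    drop <- fit$loglik - vapply(log(grid), prof_ll, 0)
    drop <- cummax(pmax(drop, 0))  # enforce monotone profile away from MLE
    idx <- which(drop >= cut)
    if (length(idx) == 0) return(grid[n_grid])
    i <- idx[1]
    lo_d <- if (i == 1) 0 else drop[i - 1]
    lo_e <- if (i == 1) fit$ec50 else grid[i - 1]
    fr <- (cut - lo_d) / (drop[i] - lo_d)
    exp(log(lo_e) + fr * (log(grid[i]) - log(lo_e)))
  }
  c(lower = bound(-1), upper = bound(+1))
}

#' Rank genes by sensitivity (ascending EC50)
#'
#' Orders genes by the EC50 of their converged, non-flat Hill fits and scores
#' each adjacent-or-not pair's order. With `confidence = "profile"`,
#' profile-likelihood intervals are computed and a pair is "high" confidence
#' when the intervals are disjoint; with `"bootstrap"`, per-dose counts are
#' resampled from the fitted per-dose proportions and the order frequency
#' reported; `"none"` skips confidence scoring.
#'
#' @param fits named list of `hill_fit` objects (one per gene).
#' @param confidence `"profile"`, `"bootstrap"` or `"none"`.
#' @param nboot bootstrap replicates when `confidence = "bootstrap"`.
#' @param level CI coverage for the profile method.
#' @return list: `ranking` data.frame (gene, ec50, lower, upper) in ascending
#'   EC50 order, `pairs` data.frame of pairwise order calls, `excluded`
#'   (genes with flat/degenerate/unconverged fits).
#' @export
rank_sensitivity <- function(fits, confidence = c("profile", "bootstrap", "none"),
                             nboot = 200, level = 0.95) {
  confidence <- match.arg(confidence)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    stop("fits must be a named list (one name per gene)")
  }
  ok <- vapply(fits, function(f) f$status == "ok" && f$converged, TRUE)
  excluded <- names(fits)[!ok]
  fits <- fits[ok]
  if (length(fits) < 2) {
    return(list(ranking = data.frame(gene = names(fits),
                                     ec50 = vapply(fits, `[[`, 0, "ec50"),
                                     lower = NA_real_, upper = NA_real_),
                pairs = NULL, excluded = excluded, flagged = length(fits) < 1))
  }
  ec <- vapply(fits, `[[`, 0, "ec50")
  ord <- order(ec)
  ci <- if (confidence == "profile") {
    t(vapply(fits, profile_ci_ec50, c(0, 0), level = level))
  } else {
    matrix(NA_real_, length(fits), 2)
  }
  ranking <- data.frame(gene = names(fits)[ord], ec50 = ec[ord],
                        lower = ci[ord, 1], upper = ci[ord, 2],
                        stringsAsFactors = FALSE)
  pairs <- NULL
  cmb <- utils::combn(seq_along(ord), 2)
  pr <- lapply(seq_len(ncol(cmb)), function(i) {
    a <- ord[cmb[1, i]]; b <- ord[cmb[2, i]]
    conf <- switch(confidence,
      none = NA_character_,
      profile = if (!any(is.na(ci[c(a, b), ])) && ci[a, 2] < ci[b, 1])
        "high" else "low",
      bootstrap = {
        fa <- fits[[a]]; fb <- fits[[b]]
        hits <- 0L
        for (r in seq_len(nboot)) {
          ka <- stats::rbinom(length(fa$n), fa$n, pmin(pmax(fa$k / fa$n, 0), 1))
          kb <- stats::rbinom(length(fb$n), fb$n, pmin(pmax(fb$k / fb$n, 0), 1))
          ra <- tryCatch(fit_hill(fa$doses, ka, fa$n, n_starts = 4),
                         error = function(e) NULL)
          rb <- tryCatch(fit_hill(fb$doses, kb, fb$n, n_starts = 4),
                         error = function(e) NULL)
          if (!is.null(ra) && !is.null(rb) && ra$status == "ok" &&
              rb$status == "ok" && ra$ec50 < rb$ec50) hits <- hits + 1L
        }
        sprintf("%.2f", hits / nboot)
      })
    data.frame(first = names(fits)[a], second = names(fits)[b],
               ec50_first = ec[a], ec50_second = ec[b],
               confidence = conf, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pr)
  list(ranking = ranking, pairs = pairs, excluded = excluded, flagged = FALSE)
}

#' Posterior-predictive dispersion check of the quantal fit
#'
#' Compares the observed per-dose deviance (saturated vs fitted model) with
#' its parametric-bootstrap distribution under the fitted Hill-binomial
#' model. A small tail probability indicates extra-binomial variation, i.e. a
#' departure from pure all-or-none activation. Skipped (with a flag) for
#' flat/degenerate fits and when any dose has fewer than `min_n` cells.
#'
#' @param fit a converged `hill_fit`.
#' @param B bootstrap replicates (default 200).
#' @param min_n per-dose sample-size floor below which the check is skipped.
#' @return list: `performed`, `skip_reason`, `tail_prob`, `deviance_obs`,
#'   `deviance_null` (bootstrap draws).
#' @export
posterior_predictive_check <- function(fit, B = 200, min_n = 5) {
  stopifnot(inherits(fit, "hill_fit"))
  if (fit$status != "ok" || !fit$converged) {
    return(list(performed = FALSE, skip_reason = "fit not usable",
                tail_prob = NA_real_, deviance_obs = NA_real_,
                deviance_null = numeric()))
  }
  if (min(fit$n) < min_n) {
    return(list(performed = FALSE, skip_reason = "sample size below floor",
                tail_prob = NA_real_, deviance_obs = NA_real_,
                deviance_null = numeric()))
  }
  p_fit <- hill_prob(fit$doses, fit$p0, fit$pmax, fit$ec50, fit$h)
  dev_null <- numeric(B)
  for (b in seq_len(B)) {
    kb <- stats::rbinom(length(fit$n), fit$n, p_fit)
    rb <- fit_hill(fit$doses, kb, fit$n, n_starts = 4, flat_alpha = 0)
    dev_null[b] <- if (is.finite(rb$deviance)) rb$deviance else NA_real_
  }
  dev_null <- dev_null[is.finite(dev_null)]
  tail_prob <- mean(dev_null >= fit$deviance)
  list(performed = TRUE, skip_reason = NA_character_, tail_prob = tail_prob,
       deviance_obs = fit$deviance, deviance_null = dev_null)
}
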