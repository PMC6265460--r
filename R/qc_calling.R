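# Well QC, expression calling and modality assessment.

#' Remove failed wells by the housekeeping criterion
#'
#' Wells in which every listed housekeeping gene is undetected (expression 0)
#' represent damaged cells, debris or empty capture sites and are removed.
#' Wells expressing at least one housekeeping gene are retained; the per-well
#' housekeeping detection table is returned so stricter rules can be applied
#' downstream.
#'
#' @param e an `expression_matrix`.
#' @param housekeeping housekeeping gene names; default the panel's
#'   housekeeping-role genes (Eef1a, H2fz, Rps11, Rps25 on the standard chip).
#' @return list: `expression` (filtered matrix) and `report` (class
#'   `qc_report`) with `retained`, `removed` (with reason codes) and the
#'   per-well housekeeping detection table `hk_table`.
#' @export
filter_failed_wells <- function(e, housekeeping = NULL) {
  stopifnot(inherits(e, "expression_matrix"))
  if (is.null(housekeeping)) {
    housekeeping <- e$genes$marker_id[e$genes$role == "housekeeping"]
  }
  if (length(housekeeping) == 0) stop("housekeeping gene list is empty")
  absent <- setdiff(housekeeping, colnames(e$expr))
  if (length(absent)) {
    stop("housekeeping gene(s) not in panel: ", paste(absent, collapse = ", "))
  }
  hk <- e$expr[, housekeeping, drop = FALSE] > 0
  failed <- rowSums(hk) == 0
  report <- structure(
    list(
      retained = e$cells$well_id[!failed],
      removed = data.frame(
        well_id = e$cells$well_id[failed],
        reason = rep("no_housekeeping_expression", sum(failed)),
        stringsAsFactors = FALSE
      ),
      hk_table = hk,
      housekeeping = housekeeping
    ),
    class = "qc_report"
  )
  keep <- !failed
  filtered <- expression_matrix(
    e$expr[keep, , drop = FALSE], e$cells[keep, , drop = FALSE], e$genes,
    spikes = if (!is.null(e$spikes)) e$spikes[keep, , drop = FALSE],
    max_cycle = e$max_cycle
  )
  list(expression = filtered, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d wells retained, %d removed (%s)\n",
              length(x$retained), nrow(x$removed),
              paste(x$housekeeping, collapse = "/")))
  invisible(x)
}

#' Call each cell x gene as expressing or non-expressing
#'
#' Default policy `"detected"`: a cell expresses a gene iff its expression is
#' above 0, which is exact when undetected reactions map to 0. Policy
#' `"mixture"` additionally separates a leaky off-state: per gene, a
#' two-component Gaussian mixture is fit to the detected values and a cell is
#' called expressing when its posterior probability for the upper component
#' exceeds 0.5 (undetected cells are always non-expressing). Genes with fewer
#' than `min_detected` detected values, or where the mixture degenerates,
#' fall back to the detected rule.
#'
#' @param e a QC-filtered `expression_matrix`.
#' @param policy `"detected"` or `"mixture"`.
#' @param min_detected minimum detected cells for a per-gene mixture fit.
#' @return an object of class `call_matrix`: binary `calls` (cells x genes),
#'   the policy used, and the cell/gene tables.
#' @export
call_expressing <- function(e, policy = c("detected", "mixture"),
                            min_detected = 10) {
  stopifnot(inherits(e, "expression_matrix"))
  policy <- match.arg(policy)
  calls <- (e$expr > 0) * 1L
  if (policy == "mixture") {
    for (j in seq_len(ncol(e$expr))) {
      v <- e$expr[, j]
      det <- v > 0
      if (sum(det) < min_detected) next
      fit <- .gauss2_em(v[det])
      if (is.null(fit)) next
      hi <- which.max(fit$mu)
      post <- .gauss2_posterior(v[det], fit)[, hi]
      calls[det, j] <- as.integer(post > 0.5)
    }
  }
  structure(
    list(calls = calls, policy = policy, cells = e$cells, genes = e$genes,
         modality = NULL),
    class = "call_matrix"
  )
}

#' @export
print.call_matrix <- function(x, ...) {
  cat(sprintf("call_matrix: %d cells x %d genes, policy '%s', %.1f%% expressing\n",
              nrow(x$calls), ncol(x$calls), x$policy, 100 * mean(x$calls)))
  invisible(x)
}

# two-component univariate Gaussian EM; returns NULL on degeneracy
.gauss2_em <- function(x, max_iter = 200, tol = 1e-8) {
  if (stats::sd(x) == 0) return(NULL)
  q <- stats::quantile(x, c(0.25, 0.75))
  mu <- as.numeric(q); sg <- rep(max(stats::sd(x) / 2, 1e-3), 2); w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
    g <- d1 / tot
    w <- c(mean(g), 1 - mean(g))
    if (min(w) < 1e-4) return(NULL)
    mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    sg <- sqrt(c(sum(g * (x - mu[1])^2) / sum(g),
                 sum((1 - g) * (x - mu[2])^2) / sum(1 - g)))
    sg <- pmax(sg, 1e-3)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sg, w = w)
}

.gauss2_posterior <- function(x, fit) {
  d <- cbind(fit$w[1] * stats::dnorm(x, fit$mu[1], fit$sigma[1]),
             fit$w[2] * stats::dnorm(x, fit$mu[2], fit$sigma[2]))
  d / rowSums(d)
}

#' Assess whether a gene's single-cell distribution is bimodal
#'
#' Compares a one-component Gaussian against a two-component model in which
#' undetected cells form a point mass at the expression floor and detected
#' cells are Gaussian. Both models are scored with a binned (interval)
#' likelihood at the instrument's Ct resolution, making the discrete floor
#' mass and the continuous component commensurable, and compared by BIC. The
#' label is `bimodal` when the two-component model wins and the minor mode
#' holds at least `minor_floor` of the cells; `indeterminate` below
#' `min_cells` values (never an error).
#'
#' @param values per-gene expression vector (0 = undetected).
#' @param min_cells sample-size floor (default 20).
#' @param minor_floor minimum minor-mode fraction for a bimodal call.
#' @param resolution Ct resolution used as the likelihood bin width.
#' @return list: `label` in unimodal/bimodal/indeterminate, `n`, `n_zero`,
#'   `bic_1`, `bic_2`, `minor_fraction`.
#' @export
assess_modality <- function(values, min_cells = 20, minor_floor = 0.05,
                            resolution = 0.1) {
  values <- values[!is.na(values)]
  n <- length(values)
  out <- list(label = "indeterminate", n = n, n_zero = sum(values == 0),
              bic_1 = NA_real_, bic_2 = NA_real_, minor_fraction = NA_real_)
  if (n < min_cells) return(out)
  if (stats::sd(values) == 0) { out$label <- "unimodal"; return(out) }

  binned_ll <- function(x, mu, sg) {
    sg <- max(sg, resolution / 2)
    p <- stats::pnorm(x + resolution / 2, mu, sg) -
         stats::pnorm(x - resolution / 2, mu, sg)
    sum(log(pmax(p, 1e-300)))
  }
  ll1 <- binned_ll(values, mean(values), stats::sd(values))
  out$bic_1 <- -2 * ll1 + 2 * log(n)

  pos <- values[values > 0]
  n0 <- n - length(pos)
  if (n0 == 0 || length(pos) == 0) {
    # no floor mass (or nothing detected): one-component description stands
    out$label <- "unimodal"
    out$minor_fraction <- 0
    return(out)
  }
  w <- n0 / n
  ll2 <- n0 * log(w) + length(pos) * log(1 - w) +
    binned_ll(pos, mean(pos), if (length(pos) > 1) stats::sd(pos) else resolution)
  out$bic_2 <- -2 * ll2 + 3 * log(n)
  out$minor_fraction <- min(w, 1 - w)
  out$label <- if (out$bic_2 < out$bic_1 && out$minor_fraction >= minor_floor) {
    "bimodal"
  } else {
    "unimodal"
  }
  out
}

#' Label the modality of every gene in a call matrix
#'
#' Convenience wrapper running [assess_modality()] per gene and storing the
#' labels on the call matrix.
#'
#' @param calls a `call_matrix`.
#' @param e the matching `expression_matrix`.
#' @param ... passed to [assess_modality()].
#' @return the `call_matrix` with a named `modality` vector filled in.
#' @export
label_modality <- function(calls, e, ...) {
  stopifnot(inherits(calls, "call_matrix"), inherits(e, "expression_matrix"))
  calls$modality <- vapply(
    colnames(e$expr),
    function(g) assess_modality(e$expr[, g], ...)$label,
    character(1)
  )
  calls
}
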