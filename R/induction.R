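# Per-condition induction statistics: activation probabilities with binomial
# errors, induced-level summaries and their dose invariance, time-point
# contrasts, and co-induction overlaps.

#' Summarize induction per gene and condition
#'
#' For every gene x (dose, time point) combination: the number of retained
#' cells, the number expressing, the activation probability estimate
#' `p_hat = k / n` with its binomial standard deviation, and the mean/SD
#' expression over expressing cells only (the induced level). The binomial SD
#' is reported on the proportion scale,
#' `sqrt(p_hat * (1 - p_hat) / n)`, matching error bars drawn on
#' percent-expressing plots; `sd_scale = "count"` gives
#' `sqrt(n * p_hat * (1 - p_hat))`.
#'
#' @param calls a `call_matrix`.
#' @param e the matching `expression_matrix` (same cells and genes).
#' @param genes genes to summarize; default the regulated panel genes.
#' @param sd_scale `"proportion"` (default) or `"count"`.
#' @return data.frame: gene, dose_nM, time_min, n_cells, n_expressing, p_hat,
#'   binom_sd, induced_mean, induced_sd. Conditions with no expressing cells
#'   have `induced_mean`/`induced_sd` set to `NA` (flagged absent).
#' @export
summarize_induction <- function(calls, e, genes = NULL,
                                sd_scale = c("proportion", "count")) {
  stopifnot(inherits(calls, "call_matrix"), inherits(e, "expression_matrix"))
  sd_scale <- match.arg(sd_scale)
  if (!identical(dim(calls$calls), dim(e$expr)) ||
      !identical(rownames(calls$calls), rownames(e$expr))) {
    stop("call matrix and expression matrix do not share cells/genes")
  }
  if (is.null(genes)) {
    genes <- calls$genes$marker_id[calls$genes$role == "regulated"]
    if (length(genes) == 0) genes <- calls$genes$marker_id
  }
  absent <- setdiff(genes, colnames(calls$calls))
  if (length(absent)) stop("gene(s) not present: ", paste(absent, collapse = ", "))
  cond <- interaction(calls$cells$dose_nM, calls$cells$time_min, drop = TRUE)
  levels_df <- unique(data.frame(dose_nM = calls$cells$dose_nM,
                                 time_min = calls$cells$time_min))
  levels_df <- levels_df[order(levels_df$time_min, levels_df$dose_nM), ]
  rows <- list()
  for (g in genes) {
    for (i in seq_len(nrow(levels_df))) {
      sel <- calls$cells$dose_nM == levels_df$dose_nM[i] &
             calls$cells$time_min == levels_df$time_min[i]
      n <- sum(sel)
      k <- if (n > 0) sum(calls$calls[sel, g]) else 0L
      p_hat <- if (n > 0) k / n else NA_real_
      bsd <- if (n > 0) {
        if (sd_scale == "proportion") sqrt(p_hat * (1 - p_hat) / n)
        else sqrt(n * p_hat * (1 - p_hat))
      } else NA_real_
      ind <- e$expr[sel, g][calls$calls[sel, g] == 1]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g,
        dose_nM = levels_df$dose_nM[i],
        time_min = levels_df$time_min[i],
        n_cells = n,
        n_expressing = k,
        p_hat = p_hat,
        binom_sd = bsd,
        induced_mean = if (length(ind) >= 1) mean(ind) else NA_real_,
        induced_sd = if (length(ind) >= 2) stats::sd(ind) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("induction_summary", class(out))
  out
}

#' Test dose-invariance of the induced expression level
#'
#' One-way fixed-effects analysis of variance of expressing-cell expression
#' values across dose groups, asking whether the level of the on state moves
#' with dose (under quantal activation it should not). Dose groups with fewer
#' than `min_cells` expressing cells are dropped and reported.
#'
#' @param e an `expression_matrix`.
#' @param calls the matching `call_matrix`.
#' @param gene gene to test.
#' @param doses dose levels to compare; default all doses present.
#' @param time_min restrict to one time point (default: all cells pooled).
#' @param min_cells minimum expressing cells per group (default 2).
#' @return list: `performed`, `F`, `df`, `p_value`, `groups` (per-dose n),
#'   `dropped` (doses below the floor).
#' @export
test_level_invariance <- function(e, calls, gene, doses = NULL,
                                  time_min = NULL, min_cells = 2) {
  stopifnot(inherits(e, "expression_matrix"), inherits(calls, "call_matrix"))
  if (!gene %in% colnames(e$expr)) stop("gene not present: ", gene)
  sel <- rep(TRUE, nrow(e$expr))
  if (!is.null(time_min)) sel <- sel & e$cells$time_min %in% time_min
  if (is.null(doses)) doses <- sort(unique(e$cells$dose_nM[sel]))
  vals <- list(); ns <- integer(); dropped <- numeric()
  for (d in doses) {
    v <- e$expr[sel & e$cells$dose_nM == d, gene]
    v <- v[calls$calls[sel & e$cells$dose_nM == d, gene] == 1]
    if (length(v) >= min_cells) {
      vals[[as.character(d)]] <- v
      ns <- c(ns, length(v))
    } else {
      dropped <- c(dropped, d)
    }
  }
  if (length(vals) < 2) {
    return(list(performed = FALSE, F = NA_real_, df = c(NA, NA),
                p_value = NA_real_,
                groups = stats::setNames(ns, names(vals)), dropped = dropped))
  }
  y <- unlist(vals, use.names = FALSE)
  grp <- factor(rep(names(vals), vapply(vals, length, 1L)))
  fit <- stats::aov(y ~ grp)
  an <- summary(fit)[[1]]
  list(performed = TRUE,
       F = an[["F value"]][1],
       df = c(an[["Df"]][1], an[["Df"]][2]),
       p_value = an[["Pr(>F)"]][1],
       groups = stats::setNames(ns, names(vals)),
       dropped = dropped)
}

#' Contrast expressing fractions against a baseline time point
#'
#' Two-proportion test of each time point against the baseline (exact
#' conditional test on the 2x2 table by default; `method = "approx"` uses the
#' normal approximation with continuity correction).
#'
#' @param s an `induction_summary`.
#' @param gene gene to contrast.
#' @param baseline_timepoint baseline time (min), e.g. -1.
#' @param dose restrict to one dose; required when the summary spans several
#'   doses unless `pool_doses = TRUE`.
#' @param pool_doses sum counts across doses within each time point.
#' @param method `"exact"` or `"approx"`.
#' @param alpha significance level for the flag (default 0.05).
#' @return data.frame: time_min, n, k, p_hat, baseline_p, diff, p_value,
#'   significant. Time points with zero cells are flagged absent (`NA`).
#' @export
compare_timepoints <- function(s, gene, baseline_timepoint, dose = NULL,
                               pool_doses = FALSE,
                               method = c("exact", "approx"), alpha = 0.05) {
  method <- match.arg(method)
  rows <- s[s$gene == gene, , drop = FALSE]
  if (nrow(rows) == 0) stop("gene not in summary: ", gene)
  if (!is.null(dose)) rows <- rows[rows$dose_nM %in% dose, , drop = FALSE]
  if (pool_doses) {
    agg <- stats::aggregate(cbind(n_cells, n_expressing) ~ time_min,
                            data = rows, FUN = sum)
    rows <- data.frame(time_min = agg$time_min, n_cells = agg$n_cells,
                       n_expressing = agg$n_expressing)
  } else if (length(unique(rows$dose_nM)) > 1) {
    stop("summary spans several doses; pass `dose` or set pool_doses = TRUE")
  }
  b <- rows[rows$time_min == baseline_timepoint, , drop = FALSE]
  if (nrow(b) == 0 || b$n_cells[1] < 1) stop("baseline time point has no cells")
  kb <- b$n_expressing[1]; nb <- b$n_cells[1]
  others <- rows[rows$time_min != baseline_timepoint, , drop = FALSE]
  res <- lapply(seq_len(nrow(others)), function(i) {
    k <- others$n_expressing[i]; n <- others$n_cells[i]
    if (n == 0) {
      return(data.frame(time_min = others$time_min[i], n = 0L, k = 0L,
                        p_hat = NA_real_, baseline_p = kb / nb,
                        diff = NA_real_, p_value = NA_real_,
                        significant = NA))
    }
    p <- if (method == "exact") {
      stats::fisher.test(matrix(c(k, n - k, kb, nb - kb), 2))$p.value
    } else {
      suppressWarnings(
        stats::prop.test(c(k, kb), c(n, nb))$p.value
      )
    }
    data.frame(time_min = others$time_min[i], n = n, k = k,
               p_hat = k / n, baseline_p = kb / nb,
               diff = k / n - kb / nb, p_value = p,
               significant = p < alpha)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Count cells in every co-induction membership region
#'
#' For a set of k genes, counts cells in each of the 2^k membership regions
#' (including the none-region), i.e. the numbers behind a k-way Venn diagram.
#'
#' @param calls a `call_matrix`.
#' @param genes 2 to 6 distinct gene names present in the calls.
#' @return data.frame with one logical column per gene, a `region` pattern
#'   string, and `n_cells`; the counts sum to the number of retained cells.
#' @export
coinduction_overlap <- function(calls, genes) {
  stopifnot(inherits(calls, "call_matrix"))
  if (anyDuplicated(genes)) stop("duplicate genes in list")
  k <- length(genes)
  if (k < 2 || k > 6) stop("need between 2 and 6 genes")
  absent <- setdiff(genes, colnames(calls$calls))
  if (length(absent)) stop("gene(s) not present: ", paste(absent, collapse = ", "))
  m <- calls$calls[, genes, drop = FALSE] == 1
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k), KEEP.OUT.ATTRS = FALSE)
  names(patterns) <- genes
  # encode each cell's membership as an integer and tabulate
  code <- as.integer(m %*% 2^(seq_len(k) - 1))
  pat_code <- as.integer(as.matrix(patterns) %*% 2^(seq_len(k) - 1))
  cnt <- tabulate(code + 1L, nbins = 2^k)
  out <- patterns
  out$region <- apply(patterns, 1, function(r) {
    on <- genes[as.logical(r)]
    if (length(on) == 0) "none" else paste(on, collapse = "+")
  })
  out$n_cells <- cnt[pat_code + 1L]
  out
}
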