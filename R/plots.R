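# Figure helpers for the analysis drivers. ggplot2 is in Suggests; each
# function checks for it at call time.

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
}

#' Scatter plot of single-cell expression with the floor mass
#'
#' Vertical scatter per dose with non-expressing cells at the floor,
#' mirroring per-gene single-cell dot plots.
#'
#' @param e an `expression_matrix`.
#' @param gene gene to plot.
#' @param time_min optional time-point filter.
#' @return a ggplot object.
#' @export
plot_expression_scatter <- function(e, gene, time_min = NULL) {
  .need_ggplot()
  sel <- if (is.null(time_min)) rep(TRUE, nrow(e$expr)) else
    e$cells$time_min %in% time_min
  df <- data.frame(dose = factor(e$cells$dose_nM[sel]),
                   expression = e$expr[sel, gene])
  ggplot2::ggplot(df, ggplot2::aes(x = dose, y = expression)) +
    ggplot2::geom_jitter(width = 0.25, height = 0, size = 0.8, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          colour = "darkgreen", linetype = "dotted") +
    ggplot2::labs(x = "GnRH (nM)", y = "expression (41 - Ct)", title = gene)
}

#' Percent-expressing dose curves with binomial error bars
#'
#' @param s an `induction_summary`.
#' @param genes genes to draw (default all in the summary).
#' @param fits optional named list of `hill_fit` objects to overlay.
#' @param time_min optional time-point filter.
#' @return a ggplot object.
#' @export
plot_percent_expressing <- function(s, genes = unique(s$gene), fits = NULL,
                                    time_min = NULL) {
  .need_ggplot()
  df <- s[s$gene %in% genes, ]
  if (!is.null(time_min)) df <- df[df$time_min %in% time_min, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = dose_nM, y = 100 * p_hat,
                                        colour = gene)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = 100 * (p_hat - binom_sd),
                                        ymax = 100 * (p_hat + binom_sd)),
                           width = 0.15) +
    ggplot2::labs(x = "GnRH (nM)", y = "% expressing cells")
  if (!is.null(fits)) {
    grid <- seq(0, max(df$dose_nM), length.out = 200)
    cv <- do.call(rbind, lapply(names(fits), function(g) {
      f <- fits[[g]]
      if (f$status != "ok") return(NULL)
      data.frame(gene = g, dose_nM = grid,
                 p = 100 * hill_prob(grid, f$p0, f$pmax, f$ec50, f$h))
    }))
    if (!is.null(cv)) {
      p <- p + ggplot2::geom_line(data = cv,
                                  ggplot2::aes(y = p, colour = gene),
                                  linetype = "dashed")
    }
  }
  p
}

#' Induced-level bars with standard deviations
#'
#' Mean expression over expressing cells per dose, the summary whose
#' dose-invariance the quantal model predicts.
#'
#' @param s an `induction_summary`.
#' @param gene gene to draw.
#' @param time_min optional time-point filter.
#' @return a ggplot object.
#' @export
plot_induced_level <- function(s, gene, time_min = NULL) {
  .need_ggplot()
  df <- s[s$gene == gene, ]
  if (!is.null(time_min)) df <- df[df$time_min %in% time_min, ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(dose_nM), y = induced_mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = induced_mean - induced_sd,
                                        ymax = induced_mean + induced_sd),
                           width = 0.3) +
    ggplot2::labs(x = "GnRH (nM)", y = "mean expression in expressing cells",
                  title = gene)
}

#' Heat-strip of cells ordered by cell-cycle progression
#'
#' @param scores a `phase_scores`.
#' @return a ggplot object (phases x cells tile plot).
#' @export
plot_phase_strip <- function(scores) {
  .need_ggplot()
  ord <- order_by_progression(scores)
  m <- scores$normalized[ord, , drop = FALSE]
  df <- expand.grid(cell = seq_len(nrow(m)), phase = colnames(m),
                    KEEP.OUT.ATTRS = FALSE)
  df$score <- as.vector(m)
  df$phase <- factor(df$phase, levels = rev(scores$phases))
  ggplot2::ggplot(df, ggplot2::aes(x = cell, y = phase, fill = score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "cells (aligned by cycle progression)", y = NULL)
}
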