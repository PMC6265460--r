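# Sample-level reproducibility reports: log2(CPM + 1) transform and pairwise
# Pearson correlation matrices.

#' Log counts-per-million transform
#'
#' `log2(1e6 * count / total + 1)` per gene, computed per sample over the
#' genes present in the matrix. Scale-invariant: doubling every count of a
#' sample leaves the result unchanged.
#'
#' @param counts non-negative numeric vector (one sample) or genes x samples
#'   matrix.
#' @return transformed vector, or a matrix with all-zero samples dropped and
#'   listed in the `"excluded"` attribute.
#' @export
log_cpm <- function(counts) {
  if (is.matrix(counts) || is.data.frame(counts)) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be non-negative")
    tot <- colSums(counts)
    dead <- tot == 0
    out <- log2(sweep(counts[, !dead, drop = FALSE], 2, tot[!dead], "/") * 1e6 + 1)
    attr(out, "excluded") <- colnames(counts)[dead]
    return(out)
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot == 0) stop("all-zero sample: transform undefined")
  log2(counts / tot * 1e6 + 1)
}

#' Pairwise Pearson correlation report
#'
#' Product-moment correlation computed from the definition,
#' `r = sum((x - mean(x)) (y - mean(y))) / sqrt(sum((x - mean(x))^2)
#' sum((y - mean(y))^2))`, for every sample pair. The diagonal is exactly 1;
#' pairs involving a zero-variance profile are flagged absent (`NA`), not 0.
#'
#' @param profiles genes x samples matrix (typically [log_cpm()] output).
#' @param transform free-text descriptor stored in the report.
#' @return object of class `correlation_report`: `cor` (symmetric matrix),
#'   `n_genes`, `transform`, `zero_variance` (sample names).
#' @export
pairwise_pearson <- function(profiles, transform = "log2(CPM+1)") {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2) stop("need at least 2 samples")
  ns <- ncol(profiles)
  ctr <- sweep(profiles, 2, colMeans(profiles))
  ss <- colSums(ctr^2)
  zv <- ss == 0
  r <- matrix(NA_real_, ns, ns, dimnames = list(colnames(profiles),
                                                colnames(profiles)))
  for (i in seq_len(ns)) {
    for (j in i:ns) {
      if (i == j) { r[i, j] <- 1; next }
      if (zv[i] || zv[j]) next
      v <- sum(ctr[, i] * ctr[, j]) / sqrt(ss[i] * ss[j])
      r[i, j] <- r[j, i] <- v
    }
  }
  structure(
    list(cor = r, n_genes = nrow(profiles), transform = transform,
         zero_variance = colnames(profiles)[zv]),
    class = "correlation_report"
  )
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report: %d samples, %d genes, transform %s\n",
              ncol(x$cor), x$n_genes, x$transform))
  off <- x$cor[upper.tri(x$cor)]
  if (length(off)) {
    cat(sprintf("  off-diagonal range: [%.4f, %.4f]\n",
                min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  }
  invisible(x)
}
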