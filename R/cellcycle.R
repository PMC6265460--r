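# Cell-cycle phase scoring.
#
# Gene-set scoring in the style popularized for droplet single-cell data:
# per-cell mean log-normalized expression over each phase's marker set, a
# refinement pass dropping genes that do not track their phase's preliminary
# score, then a two-stage z-normalization (across cells per phase, then
# across phases per cell) before assignment and cyclic ordering.

CANONICAL_PHASES <- c("G1/S", "S", "G2/M", "M", "M/G1")

#' Default cell-cycle phase gene sets
#'
#' Loads the packaged five-phase marker table (editable two-column CSV:
#' gene, phase). The shipped set is a curated list of canonical cycle markers
#' (e.g. Mcm5/Pcna for G1/S, Ccnb1/Cdk1 for G2/M).
#'
#' @param path optional path to a custom CSV with columns `gene`, `phase`.
#' @return named list of character vectors in canonical phase order.
#' @export
phase_gene_sets <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cellcycle_phase_genes.csv",
                        package = "scquantal")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "phase") %in% names(tab))) {
    stop("phase gene set CSV needs columns gene, phase")
  }
  phases <- intersect(CANONICAL_PHASES, unique(tab$phase))
  phases <- c(phases, setdiff(unique(tab$phase), CANONICAL_PHASES))
  sets <- lapply(phases, function(p) tab$gene[tab$phase == p])
  names(sets) <- phases
  sets
}

#' Score cells against cell-cycle phase gene sets
#'
#' Counts are normalized to log2(CPM + 1); the preliminary score of a phase
#' is the mean over its genes present in the matrix. One refinement pass
#' keeps only genes whose expression correlates with their phase's
#' preliminary score above `refine_threshold` (all genes are kept if none
#' survive). Scores are then z-normalized across cells per phase and across
#' phases per cell; each cell is assigned the argmax phase, ties broken by
#' canonical phase order.
#'
#' @param counts cells x genes non-negative count matrix.
#' @param gene_sets named list of phase gene sets (canonical order is the
#'   order of this list); default [phase_gene_sets()].
#' @param refine_threshold correlation threshold of the refinement pass.
#' @param refine_passes number of refinement passes (default 1; 0 disables).
#' @return object of class `phase_scores`: `raw` (mean log-CPM scores),
#'   `scaled` (z across cells per phase), `normalized` (then z across phases
#'   per cell), `phase` (assigned), `progression` (rank along the cycle,
#'   0-based), `genes_used`.
#' @export
score_phases <- function(counts, gene_sets = phase_gene_sets(),
                         refine_threshold = 0.3, refine_passes = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  phases <- names(gene_sets)
  if (is.null(phases) || length(phases) < 2) stop("need >= 2 named phases")
  present <- lapply(gene_sets, intersect, y = colnames(counts))
  empty <- phases[lengths(present) == 0]
  if (length(empty)) {
    stop("no genes of phase ", paste(empty, collapse = ", "),
         " present in the matrix")
  }
  tot <- rowSums(counts)
  tot[tot == 0] <- 1  # empty cells score 0 everywhere
  lcpm <- log2(counts / tot * 1e6 + 1)

  score_of <- function(sets) {
    vapply(sets, function(g) rowMeans(lcpm[, g, drop = FALSE]), numeric(nrow(lcpm)))
  }
  used <- present
  sc <- score_of(used)
  for (pass in seq_len(refine_passes)) {
    for (i in seq_along(used)) {
      r <- suppressWarnings(
        stats::cor(lcpm[, used[[i]], drop = FALSE], sc[, i])
      )
      keep <- used[[i]][!is.na(r) & r > refine_threshold]
      if (length(keep) > 0) used[[i]] <- keep
    }
    sc <- score_of(used)
  }

  zcol <- function(m) {
    apply(m, 2, function(v) {
      s <- stats::sd(v)
      if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
  }
  scaled <- zcol(sc)
  normalized <- t(apply(scaled, 1, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  dimnames(scaled) <- dimnames(normalized) <- list(rownames(counts), phases)

  assigned <- phases[apply(normalized, 1, which.max)]  # first max = canonical
  out <- structure(
    list(raw = sc, scaled = scaled, normalized = normalized,
         phase = stats::setNames(assigned, rownames(counts)),
         progression = NULL, phases = phases, genes_used = used),
    class = "phase_scores"
  )
  out$progression <- order_by_progression(out, index_only = TRUE)
  out
}

#' Order cells by cell-cycle progression
#'
#' Sorts cells primarily by assigned phase in canonical cyclic order and
#' within a phase by the gradient toward the next phase (descending current
#' minus next-phase normalized score), giving a smooth progression. Ties are
#' broken by cell id, so the result does not depend on the input row order.
#'
#' @param scores a `phase_scores`.
#' @param index_only return the 0-based progression rank per cell (in input
#'   cell order) instead of the ordered cell ids.
#' @return ordered cell ids, or an integer vector of ranks.
#' @export
order_by_progression <- function(scores, index_only = FALSE) {
  stopifnot(inherits(scores, "phase_scores"))
  phases <- scores$phases
  nm <- names(scores$phase)
  if (is.null(nm)) nm <- as.character(seq_along(scores$phase))
  pi_ <- match(scores$phase, phases)
  nxt <- pi_ %% length(phases) + 1L
  grad <- scores$normalized[cbind(seq_along(pi_), pi_)] -
          scores$normalized[cbind(seq_along(pi_), nxt)]
  ord <- order(pi_, -grad, nm)
  if (index_only) {
    rank <- integer(length(ord))
    rank[ord] <- seq_along(ord) - 1L
    return(stats::setNames(rank, nm))
  }
  nm[ord]
}

#' Phase composition per sample group
#'
#' @param scores a `phase_scores`.
#' @param groups group label per cell (same order as the score rows).
#' @return data.frame: group, then one percentage column per phase (rows sum
#'   to 100); groups with no cells are flagged absent (`NA`).
#' @export
phase_composition <- function(scores, groups) {
  stopifnot(inherits(scores, "phase_scores"))
  if (length(groups) != length(scores$phase)) {
    stop("need one group label per cell")
  }
  groups <- as.factor(groups)
  rows <- lapply(levels(groups), function(g) {
    ph <- scores$phase[groups == g]
    if (length(ph) == 0) {
      pc <- rep(NA_real_, length(scores$phases))
    } else {
      pc <- 100 * vapply(scores$phases, function(p) mean(ph == p), 0)
    }
    df <- data.frame(group = g, n_cells = length(ph), stringsAsFactors = FALSE)
    df[scores$phases] <- as.list(pc)
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
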