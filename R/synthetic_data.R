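# Ground-truth generators.
#
# The single-cell qPCR generator implements the quantal activation model: a
# GnRH pulse at concentration c switches each cell's copy of regulated gene g
# "on" with probability p_g(c); once on, the expression level is drawn from a
# dose-independent Gaussian on the 41 - Ct scale. Housekeeping and other
# constitutive genes are always on; debris/empty wells carry no signal at all.

#' Quantal activation model parameters
#'
#' Per regulated gene: the dose-independent on-state level (mean and SD on the
#' `41 - Ct` expression scale) and a Hill-parameterized activation
#' probability, `p(c) = p0 + (pmax - p0) * c^h / (ec50^h + c^h)`. Housekeeping
#' and other constitutive genes get a level distribution only.
#'
#' The default calibration places the four immediate-early genes at
#' `p0 = 0.05`, `pmax = 0.97`, `h = 2`, with EC50s ordered
#' Egr1 (2.3 nM) < Fos (2.5) < Egr2 (3.6) < Fosb (5.0), so that the pooled
#' expressing fraction stays below 10% at 0 and 0.5 nM and above 90% at
#' 20 nM while preserving the sensitivity hierarchy Egr1 ~ Fos before
#' Egr2 ~ Fosb.
#'
#' @param regulated data.frame: gene, on_mean, on_sd, p0, pmax, ec50, h.
#' @param housekeeping data.frame: gene, mean, sd.
#' @param other data.frame: gene, mean, sd (constitutive non-housekeeping
#'   panel genes).
#' @param leak_prob probability an off-state cell still shows a weak signal
#'   ("leaky off"); 0 disables leak (the default).
#' @param leak_mean,leak_sd level distribution of leak events.
#' @param decay_60 activation-probability multiplier at +60 min relative to
#'   the +25/+35 min plateau (1 = no decay).
#' @return an object of class `quantal_params`.
#' @export
quantal_params <- function(regulated = NULL, housekeeping = NULL, other = NULL,
                           leak_prob = 0, leak_mean = 3, leak_sd = 1,
                           decay_60 = 1) {
  if (is.null(regulated)) {
    regulated <- data.frame(
      gene = c("Egr1", "Fos", "Egr2", "Fosb"),
      on_mean = c(15, 16, 14, 13),
      on_sd = c(1.5, 1.5, 1.5, 1.5),
      p0 = 0.05, pmax = 0.97,
      ec50 = c(2.3, 2.5, 3.6, 5.0),
      h = 2,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(housekeeping)) {
    housekeeping <- data.frame(
      gene = c("Eef1a", "H2fz", "Rps11", "Rps25"),
      mean = c(19, 17, 18, 18),
      sd = 1.2,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(other)) {
    n_other <- 54 - nrow(regulated) - nrow(housekeeping)
    other <- data.frame(
      gene = sprintf("Gene%02d", seq_len(n_other)),
      mean = seq(8, 16, length.out = n_other),
      sd = 1.5,
      stringsAsFactors = FALSE
    )
  }
  with(regulated, {
    if (any(p0 < 0 | p0 > pmax | pmax > 1)) {
      stop("activation probabilities must satisfy 0 <= p0 <= pmax <= 1")
    }
    if (any(on_mean <= 0 | on_sd <= 0 | ec50 <= 0 | h <= 0)) {
      stop("on_mean, on_sd, ec50 and h must all be positive")
    }
  })
  if (leak_prob < 0 || leak_prob > 1) stop("leak_prob must be in [0, 1]")
  if (decay_60 < 0 || decay_60 > 1) stop("decay_60 must be in [0, 1]")
  structure(
    list(regulated = regulated, housekeeping = housekeeping, other = other,
         leak_prob = leak_prob, leak_mean = leak_mean, leak_sd = leak_sd,
         decay_60 = decay_60),
    class = "quantal_params"
  )
}

#' Condition design for a pulse-paradigm chip
#'
#' Defaults follow the study design: GnRH doses 0/0.5/2/8/20 nM, samples at
#' -1/+25/+35/+60 min relative to the fourth pulse, 4 pulses of 5 min every
#' 2 h, 120 wells per condition.
#'
#' @param doses GnRH concentrations (nM), non-negative.
#' @param times sampling time points (min relative to the 4th pulse).
#' @param n_cells wells per dose x time condition.
#' @param qc_failure_rate fraction of debris/empty wells (independent
#'   Bernoulli per well).
#' @param pulses,pulse_interval_h,pulse_min pulse schedule.
#' @param seed default RNG seed used by [simulate_sc_qpcr()].
#' @return an object of class `condition_design`.
#' @export
condition_design <- function(doses = c(0, 0.5, 2, 8, 20),
                             times = c(-1, 25, 35, 60),
                             n_cells = 120,
                             qc_failure_rate = 0.05,
                             pulses = 4, pulse_interval_h = 2, pulse_min = 5,
                             seed = 1L) {
  if (any(doses < 0)) stop("doses must be non-negative")
  if (n_cells < 1) stop("n_cells must be at least 1")
  if (qc_failure_rate < 0 || qc_failure_rate > 1) {
    stop("qc_failure_rate must be in [0, 1]")
  }
  structure(
    list(doses = doses, times = times, n_cells = n_cells,
         qc_failure_rate = qc_failure_rate, pulses = pulses,
         pulse_interval_h = pulse_interval_h, pulse_min = pulse_min,
         seed = seed),
    class = "condition_design"
  )
}

# pulse-response kinetics: 0 before the pulse, ramp to the +25/+35 plateau,
# optional decay by +60 min. Exact kinetics are free parameters; only the
# plateau values are constrained by the assayed time points.
time_response <- function(t, decay_60 = 1) {
  f <- ifelse(t < 0, 0,
       ifelse(t < 25, t / 25,
       ifelse(t <= 35, 1,
              1 + (decay_60 - 1) * pmin((t - 35) / 25, 1))))
  f
}

#' Activation probability under the quantal model
#'
#' `p(c, t) = p0 + (pmax - p0) * Hill(c) * f(t)` where `Hill(c) =
#' c^h / (ec50^h + c^h)` and `f(t)` is 0 before the pulse, 1 on the
#' +25/+35 min plateau and `decay_60` at +60 min. Non-decreasing in dose at
#' every fixed time.
#'
#' @param params a `quantal_params`.
#' @param gene regulated gene name.
#' @param dose GnRH concentration (nM), vectorized.
#' @param time time point (min relative to the 4th pulse), vectorized.
#' @return activation probability in `[0, 1]`.
#' @export
activation_prob <- function(params, gene, dose, time = 35) {
  stopifnot(inherits(params, "quantal_params"))
  i <- match(gene, params$regulated$gene)
  if (is.na(i)) stop("not a regulated gene: ", gene)
  g <- params$regulated[i, ]
  hill <- ifelse(dose == 0, 0, dose^g$h / (g$ec50^g$h + dose^g$h))
  g$p0 + (g$pmax - g$p0) * hill * time_response(time, params$decay_60)
}

# fixed non-gene marker panel: 3 Fluidigm spikes, 8 ERCC spikes, 5 DNA
# markers, generated as constant-Ct reactions
.spike_panel <- function() {
  data.frame(
    marker_id = c(paste0("FlSpike", 1:3), sprintf("ERCC-%04d", c(3, 25, 42, 60, 84, 108, 130, 171)),
                  paste0("DNAmk", 1:5)),
    class = c(rep("fluidigm_spike", 3), rep("ercc_spike", 8), rep("dna_marker", 5)),
    role = NA_character_,
    ct = c(14, 16, 18, seq(20, 27, length.out = 8), seq(25, 29, length.out = 5)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a single-cell qPCR chip under the quantal model
#'
#' Generates a 68-marker Biomark-style Ct matrix (54 genes, 3 Fluidigm spikes,
#' 8 ERCC spikes, 5 DNA markers) for every dose x time condition in the
#' design, together with the ground truth: the per-cell x gene on/off state
#' and the per-well debris flag. Regulated genes switch on with probability
#' `activation_prob(params, gene, dose, time)`; on-state levels are Gaussian
#' on the `41 - Ct` scale and independent of dose; housekeeping and other
#' panel genes are constitutively on; debris wells have every marker at the
#' no-amplification sentinel.
#'
#' @param design a `condition_design`.
#' @param params a `quantal_params`.
#' @param seed RNG seed; defaults to the seed stored in the design.
#' @return a list of class `sc_qpcr_sim`: `ct` (a [ct_matrix()]), and `truth`
#'   with `on` (wells x genes logical matrix), `debris` (logical per well) and
#'   `prob` (wells x regulated-genes matrix of the generating probabilities).
#' @export
simulate_sc_qpcr <- function(design, params = quantal_params(),
                             seed = design$seed) {
  stopifnot(inherits(design, "condition_design"),
            inherits(params, "quantal_params"))
  set.seed(seed)
  max_cycle <- 41
  conds <- expand.grid(dose_nM = design$doses, time_min = design$times,
                       KEEP.OUT.ATTRS = FALSE)
  n_per <- design$n_cells
  n_wells <- nrow(conds) * n_per

  genes <- rbind(
    data.frame(marker_id = params$housekeeping$gene, class = "gene",
               role = "housekeeping", stringsAsFactors = FALSE),
    data.frame(marker_id = params$regulated$gene, class = "gene",
               role = "regulated", stringsAsFactors = FALSE),
    data.frame(marker_id = params$other$gene, class = "gene",
               role = "other", stringsAsFactors = FALSE)
  )
  spk <- .spike_panel()
  markers <- rbind(genes, spk[, c("marker_id", "class", "role")])

  wells <- data.frame(
    well_id = sprintf("W%05d", seq_len(n_wells)),
    dose_nM = rep(conds$dose_nM, each = n_per),
    time_min = rep(conds$time_min, each = n_per),
    treatment = ifelse(rep(conds$dose_nM, each = n_per) > 0, "GnRH", "vehicle"),
    replicate = "chip1",
    stringsAsFactors = FALSE
  )

  debris <- stats::rbinom(n_wells, 1, design$qc_failure_rate) == 1
  expr <- matrix(0, n_wells, nrow(genes),
                 dimnames = list(wells$well_id, genes$marker_id))
  on <- matrix(FALSE, n_wells, nrow(genes),
               dimnames = list(wells$well_id, genes$marker_id))

  clip <- function(x) pmin(pmax(x, 0.5), max_cycle - 0.5)
  for (j in seq_len(nrow(params$housekeeping))) {
    g <- params$housekeeping[j, ]
    expr[, g$gene] <- clip(stats::rnorm(n_wells, g$mean, g$sd))
    on[, g$gene] <- TRUE
  }
  for (j in seq_len(nrow(params$other))) {
    g <- params$other[j, ]
    expr[, g$gene] <- clip(stats::rnorm(n_wells, g$mean, g$sd))
    on[, g$gene] <- TRUE
  }
  prob <- matrix(NA_real_, n_wells, nrow(params$regulated),
                 dimnames = list(wells$well_id, params$regulated$gene))
  for (j in seq_len(nrow(params$regulated))) {
    g <- params$regulated[j, ]
    p <- activation_prob(params, g$gene, wells$dose_nM, wells$time_min)
    prob[, j] <- p
    is_on <- stats::runif(n_wells) < p
    lvl <- numeric(n_wells)
    lvl[is_on] <- clip(stats::rnorm(sum(is_on), g$on_mean, g$on_sd))
    if (params$leak_prob > 0) {
      leak <- !is_on & stats::runif(n_wells) < params$leak_prob
      lvl[leak] <- clip(stats::rnorm(sum(leak), params$leak_mean, params$leak_sd))
    }
    expr[, g$gene] <- lvl
    on[, g$gene] <- is_on
  }

  # assemble Ct: genes from expression, spikes constant; debris wells all NA
  ct <- matrix(NA_real_, n_wells, nrow(markers),
               dimnames = list(wells$well_id, markers$marker_id))
  gi <- seq_len(nrow(genes))
  ct[, gi] <- ifelse(expr > 0, max_cycle - expr, NA_real_)
  ct[, nrow(genes) + seq_len(nrow(spk))] <-
    matrix(spk$ct, n_wells, nrow(spk), byrow = TRUE)
  ct[debris, ] <- NA_real_
  on[debris, ] <- FALSE

  structure(
    list(
      ct = ct_matrix(ct, wells, markers, max_cycle = max_cycle),
      truth = list(on = on, debris = stats::setNames(debris, wells$well_id),
                   prob = prob),
      design = design, params = params, seed = seed
    ),
    class = "sc_qpcr_sim"
  )
}

#' Simulate cell-cycle count data with known phase labels
#'
#' Each cell is assigned a true phase; genes in that phase's set have their
#' sampling weight multiplied by `fold` and counts are drawn multinomially at
#' a Poisson-distributed depth. `fold = Inf` puts all mass on own-phase genes.
#'
#' @param n_cells number of cells.
#' @param gene_sets named list of character vectors (phase -> genes); default
#'   is a synthetic 5-phase panel of 15 genes per phase.
#' @param depth mean total counts per cell.
#' @param fold overexpression factor for own-phase genes.
#' @param n_background constitutive genes outside every phase set.
#' @param proportions phase mixing proportions (default uniform).
#' @param seed RNG seed.
#' @return list: `counts` (cells x genes), `phase` (true labels),
#'   `gene_sets`.
#' @export
simulate_cellcycle_counts <- function(n_cells, gene_sets = NULL, depth = 2000,
                                      fold = 4, n_background = 100,
                                      proportions = NULL, seed = 1L) {
  if (is.null(gene_sets)) {
    phases <- c("G1/S", "S", "G2/M", "M", "M/G1")
    gene_sets <- lapply(seq_along(phases), function(i) {
      sprintf("ph%d_g%02d", i, 1:15)
    })
    names(gene_sets) <- phases
  }
  if (length(gene_sets) < 2) stop("need at least 2 phases")
  if (any(lengths(gene_sets) == 0)) stop("empty phase gene set")
  if (depth <= 0) stop("depth must be positive")
  if (fold < 1) stop("fold must be >= 1")
  set.seed(seed)
  phases <- names(gene_sets)
  bg <- if (n_background > 0) sprintf("bg_g%03d", seq_len(n_background)) else character()
  all_genes <- c(unique(unlist(gene_sets)), bg)
  if (is.null(proportions)) proportions <- rep(1 / length(phases), length(phases))
  truth <- sample(phases, n_cells, replace = TRUE, prob = proportions)
  counts <- matrix(0L, n_cells, length(all_genes),
                   dimnames = list(sprintf("cell%04d", seq_len(n_cells)), all_genes))
  for (i in seq_len(n_cells)) {
    w <- rep(1, length(all_genes))
    own <- all_genes %in% gene_sets[[truth[i]]]
    if (is.infinite(fold)) {
      w[] <- 0; w[own] <- 1
    } else {
      w[own] <- fold
    }
    size <- stats::rpois(1, depth)
    if (size > 0) counts[i, ] <- stats::rmultinom(1, size, w)[, 1]
  }
  list(counts = counts, phase = truth, gene_sets = gene_sets)
}

#' Simulate correlated bulk expression profiles
#'
#' Log-normal count profiles whose population log-scale correlation between
#' any two samples equals `within_group_corr`: per-gene log2 abundance is
#' `mean_log2 + sd_log2 * (sqrt(r) * shared + sqrt(1 - r) * independent)`.
#' With `r = 1` all samples are identical.
#'
#' @param n_genes number of genes (>= 2).
#' @param n_samples number of samples (>= 2).
#' @param within_group_corr target pairwise log-scale correlation in `[0, 1]`.
#' @param mean_log2,sd_log2 log2 abundance distribution across genes.
#' @param seed RNG seed.
#' @return genes x samples matrix of counts.
#' @export
simulate_bulk_profiles <- function(n_genes, n_samples = 2,
                                   within_group_corr = 0.98,
                                   mean_log2 = 9, sd_log2 = 2, seed = 1L) {
  if (n_genes < 2) stop("n_genes must be at least 2")
  if (n_samples < 2) stop("n_samples must be at least 2")
  r <- within_group_corr
  if (r < 0 || r > 1) stop("within_group_corr must be in [0, 1]")
  set.seed(seed)
  shared <- stats::rnorm(n_genes)
  x <- matrix(0, n_genes, n_samples,
              dimnames = list(sprintf("g%05d", seq_len(n_genes)),
                              sprintf("sample%02d", seq_len(n_samples))))
  for (j in seq_len(n_samples)) {
    eps <- if (r < 1) stats::rnorm(n_genes) else 0
    x[, j] <- mean_log2 + sd_log2 * (sqrt(r) * shared + sqrt(1 - r) * eps)
  }
  round(2^x)
}
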