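# Ct-matrix container and Biomark-style CSV dialect.
#
# A CtMatrix holds one chip: wells x markers cycle-threshold values, per-well
# metadata (GnRH dose, time point relative to the 4th pulse, treatment,
# replicate), and a marker table assigning each marker a class
# (gene / fluidigm_spike / ercc_spike / dna_marker) and, for genes, a role
# (housekeeping / regulated / other). Reactions that never crossed threshold
# (no amplification) are stored as NA internally and serialized as "999".

NO_AMP_TOKENS <- c("999", "Undetermined", "")

MARKER_CLASSES <- c("gene", "fluidigm_spike", "ercc_spike", "dna_marker")
GENE_ROLES <- c("housekeeping", "regulated", "other")

#' Construct a Ct matrix object
#'
#' Bundles a wells x markers matrix of cycle-threshold values with well
#' metadata and a marker panel table. Undetected reactions (no amplification)
#' are represented as `NA`.
#'
#' @param ct numeric matrix, wells in rows, markers in columns; `NA` marks a
#'   reaction that never crossed threshold. Detected values must lie in
#'   `(0, max_cycle]`.
#' @param wells data.frame with one row per well: columns `well_id`,
#'   `dose_nM`, `time_min`, `treatment`, `replicate`.
#' @param markers data.frame with one row per marker: columns `marker_id`,
#'   `class` (one of gene, fluidigm_spike, ercc_spike, dna_marker) and `role`
#'   (housekeeping / regulated / other for genes, `NA` otherwise).
#' @param max_cycle maximum PCR cycle of the run; default 41 so that
#'   expression can be computed as `41 - Ct`.
#' @return an object of class `ct_matrix`.
#' @export
ct_matrix <- function(ct, wells, markers, max_cycle = 41) {
  ct <- as.matrix(ct)
  storage.mode(ct) <- "double"
  stopifnot(is.data.frame(wells), is.data.frame(markers))
  need_w <- c("well_id", "dose_nM", "time_min", "treatment", "replicate")
  miss <- setdiff(need_w, names(wells))
  if (length(miss)) {
    stop("well metadata is missing column(s): ", paste(miss, collapse = ", "))
  }
  need_m <- c("marker_id", "class", "role")
  miss <- setdiff(need_m, names(markers))
  if (length(miss)) {
    stop("marker table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(ct) != nrow(wells)) stop("ct rows and well metadata disagree")
  if (ncol(ct) != nrow(markers)) stop("ct columns and marker table disagree")
  if (anyDuplicated(wells$well_id)) {
    stop("duplicate well id: ",
         paste(unique(wells$well_id[duplicated(wells$well_id)]), collapse = ", "))
  }
  if (anyDuplicated(markers$marker_id)) {
    stop("duplicate marker id: ",
         paste(unique(markers$marker_id[duplicated(markers$marker_id)]), collapse = ", "))
  }
  bad <- !markers$class %in% MARKER_CLASSES
  if (any(bad)) {
    stop("unknown marker class for: ",
         paste(markers$marker_id[bad], collapse = ", "))
  }
  gene <- markers$class == "gene"
  if (any(gene & !markers$role %in% GENE_ROLES)) {
    stop("gene markers must have role housekeeping, regulated or other")
  }
  det <- ct[!is.na(ct)]
  if (length(det) && (any(det <= 0) || any(det > max_cycle))) {
    stop("detected Ct values must lie in (0, max_cycle]")
  }
  rownames(ct) <- wells$well_id
  colnames(ct) <- markers$marker_id
  structure(
    list(ct = ct, wells = wells, markers = markers, max_cycle = max_cycle),
    class = "ct_matrix"
  )
}

#' @export
print.ct_matrix <- function(x, ...) {
  cls <- table(x$markers$class)
  cat(sprintf("ct_matrix: %d wells x %d markers (max cycle %g)\n",
              nrow(x$ct), ncol(x$ct), x$max_cycle))
  cat("  markers:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  cat(sprintf("  no-amplification entries: %d (%.1f%%)\n",
              sum(is.na(x$ct)), 100 * mean(is.na(x$ct))))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

# column header encodes the panel: "<marker_id>|<class>|<role>"
.marker_header <- function(markers) {
  role <- ifelse(is.na(markers$role), "", markers$role)
  paste(markers$marker_id, markers$class, role, sep = "|")
}

.parse_marker_header <- function(hdr) {
  parts <- strsplit(hdr, "|", fixed = TRUE)
  bad <- lengths(parts) < 2L | lengths(parts) > 3L
  # a trailing empty field (spike/DNA markers have no role) is dropped by
  # strsplit; pad it back
  parts <- lapply(parts, function(p) { length(p) <- 3L; p[is.na(p)] <- ""; p })
  if (any(bad)) {
    stop("malformed marker column header: ", paste(hdr[bad], collapse = ", "),
         " (expected marker|class|role)")
  }
  data.frame(
    marker_id = vapply(parts, `[`, "", 1L),
    class = vapply(parts, `[`, "", 2L),
    role = { r <- vapply(parts, `[`, "", 3L); ifelse(r == "", NA_character_, r) },
    stringsAsFactors = FALSE
  )
}

#' Write a Ct matrix to CSV
#'
#' One row per well; metadata columns are prefixed `meta_`; each marker column
#' header is `marker|class|role`. No-amplification entries are written as
#' "999". The file round-trips through [read_ct_csv()].
#'
#' @param m a `ct_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ct_csv <- function(m, path) {
  stopifnot(inherits(m, "ct_matrix"))
  chr <- matrix(format(m$ct, trim = TRUE, digits = 15),
                nrow = nrow(m$ct), ncol = ncol(m$ct))
  chr[is.na(m$ct)] <- "999"
  if (nrow(chr) == 0) chr <- matrix(character(), 0, ncol(m$ct))
  out <- data.frame(
    well_id = m$wells$well_id,
    meta_dose_nM = m$wells$dose_nM,
    meta_time_min = m$wells$time_min,
    meta_treatment = m$wells$treatment,
    meta_replicate = m$wells$replicate,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  cm <- as.data.frame(chr, stringsAsFactors = FALSE)
  names(cm) <- .marker_header(m$markers)
  out <- cbind(out, cm)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a Ct matrix from CSV
#'
#' Parses the dialect written by [write_ct_csv()]: a `well_id` column,
#' metadata columns prefixed `meta_`, and one column per marker with header
#' `marker|class|role`. The tokens "999", "Undetermined" and an empty cell
#' all parse to the no-amplification sentinel.
#'
#' @param path CSV file path.
#' @param max_cycle maximum cycle of the run (default 41).
#' @return a `ct_matrix`.
#' @export
read_ct_csv <- function(path, max_cycle = 41) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!"well_id" %in% names(raw)) stop("missing well_id column")
  meta_cols <- grep("^meta_", names(raw), value = TRUE)
  need <- c("meta_dose_nM", "meta_time_min", "meta_treatment", "meta_replicate")
  miss <- setdiff(need, meta_cols)
  if (length(miss)) {
    stop("missing metadata column(s): ", paste(miss, collapse = ", "))
  }
  marker_cols <- names(raw)[!names(raw) %in% c("well_id", meta_cols)]
  if (anyDuplicated(marker_cols)) {
    stop("duplicated marker column: ",
         paste(unique(marker_cols[duplicated(marker_cols)]), collapse = ", "))
  }
  markers <- .parse_marker_header(marker_cols)
  wells <- data.frame(
    well_id = raw$well_id,
    dose_nM = as.numeric(raw$meta_dose_nM),
    time_min = as.numeric(raw$meta_time_min),
    treatment = raw$meta_treatment,
    replicate = raw$meta_replicate,
    stringsAsFactors = FALSE
  )
  ct <- matrix(NA_real_, nrow = nrow(raw), ncol = length(marker_cols))
  for (j in seq_along(marker_cols)) {
    v <- trimws(raw[[marker_cols[j]]])
    sent <- v %in% NO_AMP_TOKENS | is.na(v)
    num <- suppressWarnings(as.numeric(v))
    bad <- !sent & is.na(num)
    if (any(bad)) {
      stop(sprintf("non-numeric Ct in column '%s', row %d: '%s'",
                   marker_cols[j], which(bad)[1], v[which(bad)[1]]))
    }
    num[sent] <- NA_real_
    ct[, j] <- num
  }
  ct_matrix(ct, wells, markers, max_cycle = max_cycle)
}

#' Read a long-format Ct table
#'
#' Alternative input: one row per reaction with columns `well_id`, `marker_id`,
#' `ct`, plus optional metadata columns. Marker classes/roles are supplied
#' separately.
#'
#' @param path CSV with columns well_id, marker_id, ct and the `meta_` columns.
#' @param markers marker table (marker_id, class, role).
#' @param max_cycle maximum cycle of the run.
#' @return a `ct_matrix`.
#' @export
read_ct_long <- function(path, markers, max_cycle = 41) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("well_id", "marker_id", "ct")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  wid <- unique(raw$well_id)
  ct <- matrix(NA_real_, length(wid), nrow(markers),
               dimnames = list(wid, markers$marker_id))
  v <- trimws(raw$ct)
  sent <- v %in% NO_AMP_TOKENS | is.na(v)
  num <- suppressWarnings(as.numeric(v))
  if (any(!sent & is.na(num))) stop("non-numeric Ct value in long table")
  num[sent] <- NA_real_
  unknown <- setdiff(unique(raw$marker_id), markers$marker_id)
  if (length(unknown)) stop("marker not in panel: ", paste(unknown, collapse = ", "))
  ct[cbind(match(raw$well_id, wid), match(raw$marker_id, markers$marker_id))] <- num
  meta <- function(col, default) {
    mc <- paste0("meta_", col)
    if (mc %in% names(raw)) raw[[mc]][match(wid, raw$well_id)] else default
  }
  wells <- data.frame(
    well_id = wid,
    dose_nM = as.numeric(meta("dose_nM", NA_real_)),
    time_min = as.numeric(meta("time_min", NA_real_)),
    treatment = meta("treatment", NA_character_),
    replicate = meta("replicate", NA_character_),
    stringsAsFactors = FALSE
  )
  ct_matrix(ct, wells, markers, max_cycle = max_cycle)
}

#' Convert cycle thresholds to the expression scale
#'
#' Expression is computed as `max_cycle - Ct` (default `41 - Ct`), so lower
#' cycle thresholds map to higher expression; no-amplification entries map to
#' exactly 0. Only gene-class markers enter the cells x genes expression
#' matrix; spikes and DNA markers are carried in a separate sub-table on the
#' same transform.
#'
#' @param m a `ct_matrix`.
#' @param max_cycle transform constant; defaults to the value stored in `m`.
#' @return an object of class `expression_matrix` with fields `expr`
#'   (cells x genes), `cells`, `genes`, `spikes`, `max_cycle`.
#' @export
ct_to_expression <- function(m, max_cycle = m$max_cycle) {
  stopifnot(inherits(m, "ct_matrix"), max_cycle > 0)
  det <- m$ct[!is.na(m$ct)]
  if (length(det) && any(det > max_cycle)) {
    stop("Ct values exceed max_cycle; expression would be negative")
  }
  expr_all <- max_cycle - m$ct
  expr_all[is.na(m$ct)] <- 0
  is_gene <- m$markers$class == "gene"
  expression_matrix(
    expr = expr_all[, is_gene, drop = FALSE],
    cells = m$wells,
    genes = m$markers[is_gene, c("marker_id", "role")],
    spikes = expr_all[, !is_gene, drop = FALSE],
    max_cycle = max_cycle
  )
}

#' Construct an expression matrix object
#'
#' Cells x genes values on the `max_cycle - Ct` scale (0 = undetected).
#'
#' @param expr numeric matrix, cells x genes, values in `[0, max_cycle]`.
#' @param cells per-cell metadata data.frame (`well_id`, `dose_nM`,
#'   `time_min`, `treatment`, `replicate`).
#' @param genes data.frame with `marker_id` and `role`.
#' @param spikes optional matrix of non-gene markers on the same scale.
#' @param max_cycle the transform constant.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(expr, cells, genes, spikes = NULL, max_cycle = 41) {
  expr <- as.matrix(expr)
  if (any(expr < 0) || any(expr > max_cycle)) {
    stop("expression values must lie in [0, max_cycle]")
  }
  if (nrow(expr) != nrow(cells)) stop("expr rows and cell metadata disagree")
  if (ncol(expr) != nrow(genes)) stop("expr columns and gene table disagree")
  rownames(expr) <- cells$well_id
  colnames(expr) <- genes$marker_id
  structure(
    list(expr = expr, cells = cells, genes = genes, spikes = spikes,
         max_cycle = max_cycle),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes (scale %g - Ct)\n",
              nrow(x$expr), ncol(x$expr), x$max_cycle))
  cat(sprintf("  detected entries: %.1f%%\n", 100 * mean(x$expr > 0)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$expr)

#' Export an expression matrix to CSV
#'
#' @param e an `expression_matrix`.
#' @param path output CSV; cells in rows, genes in columns, metadata columns
#'   prefixed `meta_`.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(e, path) {
  stopifnot(inherits(e, "expression_matrix"))
  out <- cbind(
    data.frame(well_id = e$cells$well_id,
               meta_dose_nM = e$cells$dose_nM,
               meta_time_min = e$cells$time_min,
               meta_treatment = e$cells$treatment,
               meta_replicate = e$cells$replicate,
               stringsAsFactors = FALSE),
    as.data.frame(e$expr)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export an expression matrix as Matrix Market triples
#'
#' Writes a coordinate-format `.mtx` file (cells x genes, zeros omitted) plus
#' sidecar text files listing cell and gene ids, for interoperability with
#' sparse single-cell toolchains.
#'
#' @param e an `expression_matrix`.
#' @param prefix output path prefix; writes `<prefix>.mtx`,
#'   `<prefix>.cells.txt`, `<prefix>.genes.txt`.
#' @return the mtx path, invisibly.
#' @export
write_expression_mtx <- function(e, prefix) {
  stopifnot(inherits(e, "expression_matrix"))
  idx <- which(e$expr != 0, arr.ind = TRUE)
  mtx <- paste0(prefix, ".mtx")
  con <- file(mtx, "w")
  writeLines("%%MatrixMarket matrix coordinate real general", con)
  writeLines(sprintf("%d %d %d", nrow(e$expr), ncol(e$expr), nrow(idx)), con)
  if (nrow(idx)) {
    writeLines(sprintf("%d %d %.10g", idx[, 1], idx[, 2], e$expr[idx]), con)
  }
  close(con)
  writeLines(rownames(e$expr), paste0(prefix, ".cells.txt"))
  writeLines(colnames(e$expr), paste0(prefix, ".genes.txt"))
  invisible(mtx)
}
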