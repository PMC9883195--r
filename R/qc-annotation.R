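# Quality-control filtering and marker-score cell typing. The QC thresholds
# are the stated ones: genes expressed in at least 2 cells; cells with more
# than 100 but less than 4000 detected genes (strict bounds by default, an
# inclusive reading behind a flag). The source study additionally removed
# mitochondrial outliers by eye from a violin plot; that subjective step is
# exposed as an optional numeric mito_max cutoff (default none).

#' Quality-control filter
#'
#' Gene filter first (expressed in >= \code{min_cells_per_gene} cells), then
#' the cell filter on the gene-filtered matrix (detected genes strictly
#' between the bounds; \code{inclusive = TRUE} switches to >=/<=), then the
#' optional mitochondrial-fraction cutoff (fraction of counts in genes
#' matching \code{mito_pattern}, computed before gene filtering).
#'
#' @param m an [ExpressionMatrix].
#' @param min_cells_per_gene genes must be detected in at least this many cells.
#' @param min_genes_exclusive,max_genes_exclusive cell bounds on detected genes.
#' @param mito_max optional maximum mitochondrial fraction (default none).
#' @param inclusive treat the cell bounds as inclusive.
#' @param mito_pattern regex identifying mitochondrial genes.
#' @return The filtered [ExpressionMatrix]; attribute \code{"qc_log"} records
#'   genes/cells in and out. Warns (not errors) if all cells are removed.
#' @export
qc_filter <- function(m, min_cells_per_gene = 2, min_genes_exclusive = 100,
                      max_genes_exclusive = 4000, mito_max = NULL,
                      inclusive = FALSE, mito_pattern = "^mt-") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  counts <- m$counts
  mito_frac <- if (!is.null(mito_max)) {
    mito <- grepl(mito_pattern, m$gene_ids, ignore.case = TRUE)
    tot <- Matrix::colSums(counts)
    ifelse(tot > 0, Matrix::colSums(counts[mito, , drop = FALSE]) / tot, 0)
  } else NULL

  cells_per_gene <- Matrix::rowSums(counts > 0)
  keep_genes <- cells_per_gene >= min_cells_per_gene
  counts <- counts[keep_genes, , drop = FALSE]

  genes_per_cell <- Matrix::colSums(counts > 0)
  keep_cells <- if (inclusive)
    genes_per_cell >= min_genes_exclusive & genes_per_cell <= max_genes_exclusive
  else
    genes_per_cell > min_genes_exclusive & genes_per_cell < max_genes_exclusive
  if (!is.null(mito_frac)) keep_cells <- keep_cells & mito_frac <= mito_max
  counts <- counts[, keep_cells, drop = FALSE]

  if (ncol(counts) == 0)
    warning("qc_filter removed every cell", call. = FALSE)
  out <- ExpressionMatrix(counts, rownames(counts), colnames(counts))
  attr(out, "qc_log") <- list(
    genes_in = n_genes(m), genes_kept = nrow(counts),
    cells_in = n_cells(m), cells_kept = ncol(counts),
    params = list(min_cells_per_gene = min_cells_per_gene,
                  min_genes = min_genes_exclusive,
                  max_genes = max_genes_exclusive,
                  mito_max = mito_max, inclusive = inclusive))
  out
}

#' Marker-score cell-type assignment
#'
#' Scores each marker set per cell as the mean of its markers'
#' z-scored (across cells) log1p-normalized expression; the label is the
#' argmax, ties broken by set order; cells whose scores are all <= 0 are
#' labelled \code{"unassigned"}. Markers missing from the matrix are dropped
#' with a warning; duplicated markers within a set are collapsed.
#'
#' @param m an [ExpressionMatrix] (typically post-QC).
#' @param sets named list of marker gene vectors
#'   (default [default_marker_sets()]).
#' @return Character vector of labels, one per cell, named by barcode.
#' @export
assign_cell_types <- function(m, sets = default_marker_sets()) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!length(sets)) stop("config error: empty marker-set list", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("config error: marker sets must be named", call. = FALSE)
  x <- lognormalize(m$counts)

  # Row-wise z-score of each marker across cells; zero-variance genes score 0.
  zscore_rows <- function(rows) {
    sub <- as.matrix(x[rows, , drop = FALSE])
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, stats::sd)
    z <- (sub - mu) / ifelse(sdv > 0, sdv, Inf)
    z
  }

  scores <- matrix(NA_real_, nrow = n_cells(m), ncol = 0)
  kept_names <- character(0)
  for (nm in names(sets)) {
    mk <- unique(sets[[nm]])
    present <- intersect(mk, m$gene_ids)
    if (length(present) < length(mk))
      warning("marker set '", nm, "': dropping absent symbol(s): ",
              paste(setdiff(mk, present), collapse = ", "), call. = FALSE)
    if (!length(present)) {
      warning("marker set '", nm, "': no markers present; set skipped",
              call. = FALSE)
      next
    }
    scores <- cbind(scores, colMeans(zscore_rows(present)))
    kept_names <- c(kept_names, nm)
  }
  if (!ncol(scores))
    stop("config error: no marker set had any gene present", call. = FALSE)
  colnames(scores) <- kept_names

  best <- apply(scores, 1, function(s) {
    i <- which(s == max(s))[1]  # ties: first set in supplied order
    if (s[i] <= 0) "unassigned" else kept_names[i]
  })
  stats::setNames(best, m$barcodes)
}

#' Cell-type composition per (tissue, group) stratum
#'
#' @param meta data.frame with \code{tissue}, \code{group}, \code{cell_type}.
#' @return data.table (tissue, group, cell_type, n, pct); \code{pct} sums to
#'   100 within each stratum. Empty strata are simply absent.
#' @export
composition_table <- function(meta) {
  dt <- data.table::as.data.table(meta)
  stopifnot(all(c("tissue", "group", "cell_type") %in% names(dt)))
  agg <- dt[, list(n = .N), by = c("tissue", "group", "cell_type")]
  agg[, pct := 100 * n / sum(n), by = c("tissue", "group")]
  data.table::setorderv(agg, c("tissue", "group", "cell_type"))
  agg[]
}

#' Stratum labels in figure style
#'
#' Maps the internal tissue vocabulary to the display names
#' \code{Day 0_Blood}, \code{Day 15_Blood}, \code{Day 15_Tumor}.
#' @param tissue character vector of internal tissue codes.
#' @return Character vector of display labels.
#' @export
tissue_display <- function(tissue) {
  map <- c(blood_d0 = "Day 0_Blood", blood_d15 = "Day 15_Blood",
           tumor_d15 = "Day 15_Tumor")
  unname(map[tissue])
}
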