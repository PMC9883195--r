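# Clonotype calling, frequency computation, expansion binning and ranking.
#
# A clonotype is keyed by the sorted concatenation of its retained chains,
# "chain:v_gene:j_gene:cdr3_nt" under the default "nt+gene" strategy (the
# nucleotide level matches the mRNA-sharing interpretation of TCR-bearing
# macrophages) or "chain:v_gene:j_gene:cdr3_aa" under "aa". A clonotype's
# frequency is its clone count over all clones of the sample (TCR+ cells,
# not all cells), and the expansion bins are half-open intervals (lo, hi]:
# hyperexpanded (0.1, 1], large (0.01, 0.1], medium (0.001, 0.01],
# small (1e-4, 0.001]; anything at or below 1e-4 gets an explicit "rare"
# label so conservation invariants hold.

BIN_LEVELS <- c("hyperexpanded", "large", "medium", "small", "rare")

#' Expansion-bin frequency thresholds
#'
#' @param rare_lo,small_hi,medium_hi,large_hi,hyper_hi strictly increasing
#'   upper bounds of the rare/small/medium/large/hyperexpanded intervals.
#' @return A \code{bin_thresholds} object.
#' @export
bin_thresholds <- function(rare_lo = 1e-4, small_hi = 0.001,
                           medium_hi = 0.01, large_hi = 0.1, hyper_hi = 1) {
  thr <- c(rare_lo = rare_lo, small_hi = small_hi, medium_hi = medium_hi,
           large_hi = large_hi, hyper_hi = hyper_hi)
  if (any(diff(thr) <= 0))
    stop("thresholds must be strictly increasing", call. = FALSE)
  structure(as.list(thr), class = "bin_thresholds")
}

#' Call clonotypes from a sample's contig table
#'
#' Retains contigs with \code{is_cell}, \code{high_confidence} and
#' \code{productive} all true and chain TRA or TRB; per barcode and chain
#' keeps the highest-UMI contig (ties: higher reads, then lexicographically
#' smallest cdr3_nt); keys each barcode by its retained chain set.
#' Single-chain cells are keyed by the available chain and flagged.
#'
#' @param contigs contig table from one sample ([read_contigs()] layout).
#' @param strategy \code{"nt+gene"} (default) or \code{"aa"}.
#' @param sample_id optional sample label carried into the table.
#' @return A \code{clonotype_table}: list with \code{sample_id},
#'   \code{cells} (data.table: barcode, clonotype_key, n_chains,
#'   single_chain) and \code{clones} (data.table: clonotype_key,
#'   clone_count; frequency and bin added by [bin_clonotypes()]).
#' @export
call_clonotypes <- function(contigs, strategy = c("nt+gene", "aa"),
                            sample_id = NA_character_) {
  strategy <- match.arg(strategy)
  empty <- function() structure(
    list(sample_id = sample_id, strategy = strategy,
         cells = data.table(barcode = character(),
                            clonotype_key = character(),
                            n_chains = integer(), single_chain = logical()),
         clones = data.table(clonotype_key = character(),
                             clone_count = integer())),
    class = "clonotype_table")
  if (is.null(contigs) || !nrow(contigs)) return(empty())
  dt <- data.table::as.data.table(contigs)
  dt <- dt[dt$is_cell & dt$high_confidence & dt$productive &
             dt$chain %in% c("TRA", "TRB")]
  if (!nrow(dt)) return(empty())

  # Top contig per barcode x chain: highest UMIs, then reads, then cdr3_nt.
  data.table::setorderv(dt, c("barcode", "chain", "umis", "reads", "cdr3_nt"),
                        order = c(1L, 1L, -1L, -1L, 1L))
  dt <- dt[!duplicated(dt[, c("barcode", "chain")])]

  seq_col <- if (strategy == "nt+gene") dt$cdr3_nt else dt$cdr3_aa
  dt[, "chain_key" := paste(dt$chain, dt$v_gene, dt$j_gene, seq_col,
                            sep = ":")]
  cells <- dt[, list(
    clonotype_key = paste(sort(chain_key), collapse = ";"),
    n_chains = .N), by = "barcode"]
  cells[, "single_chain" := cells$n_chains < 2L]
  clones <- cells[, list(clone_count = .N), by = "clonotype_key"]
  data.table::setorderv(clones, "clonotype_key")
  structure(list(sample_id = sample_id, strategy = strategy,
                 cells = cells[], clones = clones[]),
            class = "clonotype_table")
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf("clonotype_table [%s]: %d cells, %d clonotypes\n",
              x$sample_id, nrow(x$cells), nrow(x$clones)))
  invisible(x)
}

#' Compute clonotype frequencies and expansion bins
#'
#' Frequency f = clone_count / total clones of the sample. Bins are
#' half-open (lo, hi]: f in (0.1, 1] is hyperexpanded, (0.01, 0.1] large,
#' (0.001, 0.01] medium, (1e-4, 0.001] small, and f <= 1e-4 rare.
#'
#' @param t a \code{clonotype_table} from [call_clonotypes()].
#' @param thr a [bin_thresholds()].
#' @return The table with \code{frequency} and \code{bin} columns filled.
#' @export
bin_clonotypes <- function(t, thr = bin_thresholds()) {
  stopifnot(inherits(t, "clonotype_table"))
  clones <- data.table::copy(t$clones)
  if (nrow(clones)) {
    f <- clones$clone_count / sum(clones$clone_count)
    if (any(f <= 0 | f > 1))
      stop("invariant error: frequency outside (0, 1]", call. = FALSE)
    clones[, "frequency" := f]
    clones[, "bin" := assign_bins(f, thr)]
  } else {
    clones[, c("frequency", "bin") := list(numeric(0), character(0))]
  }
  t$clones <- clones[]
  t
}

#' Map frequencies to expansion-bin labels
#'
#' Vectorized interval membership under the half-open (lo, hi] convention.
#'
#' @param f frequencies in (0, 1].
#' @param thr a [bin_thresholds()].
#' @return Character vector of bin labels.
#' @export
assign_bins <- function(f, thr = bin_thresholds()) {
  if (any(f <= 0 | f > thr$hyper_hi))
    stop("invariant error: frequency outside (0, ", thr$hyper_hi, "]",
         call. = FALSE)
  breaks <- c(0, thr$rare_lo, thr$small_hi, thr$medium_hi, thr$large_hi,
              thr$hyper_hi)
  as.character(cut(f, breaks = breaks, labels = rev(BIN_LEVELS), right = TRUE))
}

#' Per-cell expansion-bin labels
#'
#' Each TCR+ cell inherits its clonotype's bin; cells absent from the
#' clonotype table are labelled \code{"none"}. Barcodes present in the table
#' but missing from \code{meta} are logged as orphans and excluded.
#'
#' @param t a binned \code{clonotype_table}.
#' @param meta data.frame with at least \code{barcode} for the same sample.
#' @return data.table (barcode, bin) covering every barcode in \code{meta}.
#' @export
cell_bin_labels <- function(t, meta) {
  stopifnot(inherits(t, "clonotype_table"), "bin" %in% names(t$clones))
  cells <- merge(t$cells[, c("barcode", "clonotype_key")],
                 t$clones[, c("clonotype_key", "bin")], by = "clonotype_key")
  orphans <- setdiff(cells$barcode, meta$barcode)
  if (length(orphans))
    warning(length(orphans), " orphan clonotype barcode(s) missing from ",
            "metadata; excluded", call. = FALSE)
  out <- data.table(barcode = meta$barcode)
  out <- merge(out, cells[, c("barcode", "bin")], by = "barcode",
               all.x = TRUE, sort = FALSE)
  out[is.na(out$bin), "bin" := "none"]
  out[]
}

#' Rank clonotypes by frequency
#'
#' Descending frequency; ties broken lexicographically by clonotype key;
#' rank 1 is the largest clone.
#'
#' @param t a binned \code{clonotype_table}.
#' @return data.table (rank, clonotype_key, clone_count, frequency, bin).
#' @export
rank_clonotypes <- function(t) {
  stopifnot(inherits(t, "clonotype_table"), "frequency" %in% names(t$clones))
  r <- data.table::copy(t$clones)
  data.table::setorderv(r, c("frequency", "clonotype_key"),
                        order = c(-1L, 1L))
  r[, "rank" := seq_len(nrow(r))]
  data.table::setcolorder(r, "rank")
  r[]
}

#' Per-stratum expansion-bin composition
#'
#' Two tables per (tissue, group) stratum: the percentage of clonotypes per
#' bin and the percentage of TCR+ cells per bin. Rows sum to 100 over the
#' bins present; strata with zero TCR+ cells are omitted with a warning.
#'
#' @param tables named list of binned \code{clonotype_table}s, one per sample.
#' @param meta data.frame mapping \code{sample_id} to \code{tissue} and
#'   \code{group} (e.g. the cohort cell metadata).
#' @return List of two data.tables, \code{clonotype_level} and
#'   \code{cell_level}, with columns tissue, group, bin, count, pct.
#' @export
bin_composition <- function(tables, meta) {
  key <- unique(data.table::as.data.table(meta)[, c("sample_id", "tissue",
                                                    "group")])
  rows <- list()
  for (sid in sort(names(tables))) {
    t <- tables[[sid]]
    if (!nrow(t$clones)) next
    st <- key[key$sample_id == sid]
    if (!nrow(st))
      stop("sample '", sid, "' absent from metadata", call. = FALSE)
    rows[[sid]] <- data.table(
      tissue = st$tissue[1], group = st$group[1], bin = t$clones$bin,
      n_clonotypes = 1L, n_cells = t$clones$clone_count)
  }
  if (!length(rows)) {
    warning("no TCR+ cells in any sample", call. = FALSE)
    return(list(clonotype_level = data.table(), cell_level = data.table()))
  }
  long <- data.table::rbindlist(rows)
  summarize <- function(value_col) {
    agg <- long[, list(count = sum(get(value_col))),
                by = c("tissue", "group", "bin")]
    agg[, pct := 100 * count / sum(count), by = c("tissue", "group")]
    agg[, "bin" := factor(agg$bin, levels = BIN_LEVELS)]
    data.table::setorderv(agg, c("tissue", "group", "bin"))
    agg[, "bin" := as.character(agg$bin)]
    agg[]
  }
  list(clonotype_level = summarize("n_clonotypes"),
       cell_level = summarize("n_cells"))
}
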