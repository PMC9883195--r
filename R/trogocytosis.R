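# TCR-bearing macrophage detection and clonotype sharing with T-cell
# compartments. "TCR+" means the cell's barcode owns a retained clonotype
# (productive, high-confidence contigs surviving call_clonotypes) in the
# same sample's VDJ library — barcode matching is strictly per sample, so a
# barcode colliding across samples never matches across them.

#' Flag TCR-bearing cells by GEX/VDJ barcode intersection
#'
#' @param meta data.frame with \code{barcode} and \code{sample_id}.
#' @param tables named list of \code{clonotype_table}s keyed by sample id.
#' @return Logical vector, one flag per row of \code{meta}.
#' @export
match_barcodes <- function(meta, tables) {
  dt <- data.table::as.data.table(meta)
  flags <- logical(nrow(dt))
  for (sid in unique(dt$sample_id)) {
    t <- tables[[sid]]
    if (is.null(t)) next
    rows <- dt$sample_id == sid
    flags[rows] <- dt$barcode[rows] %in% t$cells$barcode
  }
  flags
}

#' TCR-positive macrophage fraction per stratum
#'
#' @param meta data.frame with \code{barcode}, \code{sample_id},
#'   \code{tissue}, \code{group} and a cell-type column.
#' @param flags logical TCR+ flags from [match_barcodes()].
#' @param mac_label label identifying macrophages.
#' @param type_col name of the cell-type column in \code{meta}.
#' @return data.table (tissue, group, n_macrophages, n_tcr_pos, fraction);
#'   strata without macrophages report \code{NA} fraction.
#' @export
tcr_mac_fraction <- function(meta, flags, mac_label = "Macrophage",
                             type_col = "cell_type") {
  dt <- data.table::as.data.table(meta)
  dt[, "tcr_pos" := flags]
  dt <- dt[dt[[type_col]] == mac_label]
  strata <- unique(data.table::as.data.table(meta)[, c("tissue", "group")])
  agg <- dt[, list(n_macrophages = .N, n_tcr_pos = sum(tcr_pos)),
            by = c("tissue", "group")]
  agg <- merge(strata, agg, by = c("tissue", "group"), all.x = TRUE)
  agg[is.na(agg$n_macrophages), c("n_macrophages", "n_tcr_pos") := 0L]
  agg[, "fraction" := ifelse(agg$n_macrophages > 0,
                             agg$n_tcr_pos / agg$n_macrophages, NA_real_)]
  data.table::setorderv(agg, c("tissue", "group"))
  agg[]
}

#' Clonotype sharing between TCR+ macrophages and T-cell compartments
#'
#' Per sample, a TCR+ macrophage is Cd8-shared if its clonotype key occurs
#' among the same sample's Cd8+ T-cell clonotypes (Cd4 analogously);
#' macrophages shared with both compartments count in both shares and are
#' also reported separately (\code{n_dual}). Results are aggregated per
#' (tissue, group) and pooled (\code{tissue = "all"}).
#'
#' @param meta data.frame with \code{barcode}, \code{sample_id},
#'   \code{tissue}, \code{group} and a cell-type column.
#' @param flags logical TCR+ flags from [match_barcodes()].
#' @param tables named list of binned or unbinned \code{clonotype_table}s.
#' @param mac_label,cd4_labels,cd8_labels cell-type labels.
#' @param type_col name of the cell-type column.
#' @return data.table (tissue, group, n_tcr_mac, n_cd4_share, n_cd8_share,
#'   n_dual, cd4_share, cd8_share); shares are \code{NA} where a stratum has
#'   no TCR+ macrophage.
#' @export
shared_clonotype_fractions <- function(meta, flags, tables,
                                       mac_label = "Macrophage",
                                       cd4_labels = "Cd4_T",
                                       cd8_labels = "Cd8_T",
                                       type_col = "cell_type") {
  dt <- data.table::as.data.table(meta)
  dt[, "tcr_pos" := flags]
  # keep only the columns we need; a pre-existing clonotype_key column in the
  # metadata (e.g. the synthetic manifest) must not collide with the merge
  dt <- dt[, c("barcode", "sample_id", "tissue", "group", type_col,
               "tcr_pos"), with = FALSE]
  per_cell <- list()
  for (sid in unique(dt$sample_id)) {
    t <- tables[[sid]]
    if (is.null(t)) next
    sub <- dt[dt$sample_id == sid]
    keyed <- merge(sub, t$cells[, c("barcode", "clonotype_key")],
                   by = "barcode", all.x = TRUE, sort = FALSE)
    cd4_keys <- unique(keyed$clonotype_key[
      keyed[[type_col]] %in% cd4_labels & keyed$tcr_pos])
    cd8_keys <- unique(keyed$clonotype_key[
      keyed[[type_col]] %in% cd8_labels & keyed$tcr_pos])
    mac <- keyed[keyed[[type_col]] == mac_label & keyed$tcr_pos]
    if (!nrow(mac)) next
    mac[, "cd4" := mac$clonotype_key %in% cd4_keys]
    mac[, "cd8" := mac$clonotype_key %in% cd8_keys]
    per_cell[[sid]] <- mac[, c("tissue", "group", "cd4", "cd8")]
  }
  strata <- unique(dt[, c("tissue", "group")])
  if (!length(per_cell)) {
    warning("no TCR+ macrophages in any sample; shares undefined",
            call. = FALSE)
    out <- data.table::copy(strata)
    out[, c("n_tcr_mac", "n_cd4_share", "n_cd8_share", "n_dual") := 0L]
    out[, c("cd4_share", "cd8_share") := NA_real_]
    return(out[])
  }
  long <- data.table::rbindlist(per_cell)
  summarize <- function(d, label) {
    by_cols <- if (is.null(label)) c("tissue", "group") else "group"
    s <- d[, list(n_tcr_mac = .N, n_cd4_share = sum(cd4),
                  n_cd8_share = sum(cd8), n_dual = sum(cd4 & cd8)),
           by = eval(by_cols)]
    if (!is.null(label)) s[, "tissue" := label]
    s
  }
  out <- rbind(summarize(long, NULL), summarize(long, "all"), fill = TRUE)
  out[, "cd4_share" := ifelse(out$n_tcr_mac > 0,
                              out$n_cd4_share / out$n_tcr_mac, NA_real_)]
  out[, "cd8_share" := ifelse(out$n_tcr_mac > 0,
                              out$n_cd8_share / out$n_tcr_mac, NA_real_)]
  data.table::setcolorder(out, c("tissue", "group"))
  data.table::setorderv(out, c("tissue", "group"))
  out[]
}

#' Expansion-bin distribution among TCR+ macrophages
#'
#' @param meta data.frame with \code{barcode}, \code{sample_id},
#'   \code{tissue}, \code{group} and a cell-type column.
#' @param flags logical TCR+ flags.
#' @param bins data.table (sample_id, barcode, bin), e.g. stacked
#'   [cell_bin_labels()] output.
#' @param mac_label,type_col as in [tcr_mac_fraction()].
#' @return data.table (tissue, group, bin, n, share); shares sum to 1 within
#'   each stratum present. Strata without TCR+ macrophages are omitted.
#' @export
tcr_mac_bin_distribution <- function(meta, flags, bins,
                                     mac_label = "Macrophage",
                                     type_col = "cell_type") {
  dt <- data.table::as.data.table(meta)
  dt[, "tcr_pos" := flags]
  mac <- dt[dt[[type_col]] == mac_label & dt$tcr_pos]
  if (!nrow(mac)) {
    warning("no TCR+ macrophages; bin distribution empty", call. = FALSE)
    return(data.table(tissue = character(), group = character(),
                      bin = character(), n = integer(), share = numeric()))
  }
  mac <- merge(mac, data.table::as.data.table(bins)[, c("sample_id",
                                                        "barcode", "bin")],
               by = c("sample_id", "barcode"), all.x = TRUE, sort = FALSE)
  mac[is.na(mac$bin), "bin" := "none"]
  agg <- mac[, list(n = .N), by = c("tissue", "group", "bin")]
  agg[, share := n / sum(n), by = c("tissue", "group")]
  agg[, "bin" := factor(agg$bin, levels = c(BIN_LEVELS, "none"))]
  data.table::setorderv(agg, c("tissue", "group", "bin"))
  agg[, "bin" := as.character(agg$bin)]
  agg[]
}
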