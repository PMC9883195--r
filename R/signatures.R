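# Expression-bin-matched gene-set scoring and the M1-to-M2 polarization
# score. The scheme is the conventional single-cell "module score": genes are
# ranked by mean expression and cut into expression bins; each signature gene
# is compared against control genes drawn from its own bin, so the score is
# centred against genes of comparable abundance. Defaults n_bins = 24 and
# n_ctrl = 100 follow the ecosystem convention for this scoring scheme.
#
# Control draws are seeded by the *content* of the gene set (sorted symbols)
# combined with the user seed, never by row indices or by which argument slot
# the set arrived in. This yields three properties the tests rely on:
# invariance to gene row permutation, reproducibility across sessions, and
# exact antisymmetry of the M1-to-M2 difference score.

#' Expression-bin-matched module score
#'
#' Genes are ranked by mean expression across cells (ties broken by gene
#' symbol) and cut into \code{n_bins} equal-size bins; for each signature
#' gene \code{n_ctrl} control genes are drawn uniformly with replacement
#' from its bin; a cell's score is the mean expression of the signature
#' genes minus the mean over the pooled control draws.
#'
#' @param m an [ExpressionMatrix] (log-normalized internally:
#'   counts -> per-10k -> log1p) or an already log-scale numeric matrix with
#'   gene rownames (used as-is).
#' @param gene_set character vector of gene symbols; genes absent from the
#'   matrix are dropped with a warning, and an empty surviving set is an
#'   error naming the missing symbols.
#' @param n_bins number of expression bins.
#' @param n_ctrl control genes drawn per signature gene.
#' @param seed user seed; combined with the sorted set content to seed the
#'   control draws.
#' @param gene_set_id label carried into the result (defaults to a
#'   content-derived id).
#' @return A \code{signature_result}: list with \code{gene_set_id},
#'   \code{scores} (named per-cell numeric), \code{params} (n_bins, n_ctrl,
#'   seed, normalization tag) and \code{controls} (the realized control
#'   draws per signature gene, for oracle checks).
#' @export
module_score <- function(m, gene_set, n_bins = 24, n_ctrl = 100, seed = 0,
                         gene_set_id = NULL) {
  if (inherits(m, "ExpressionMatrix")) {
    x <- lognormalize(m$counts)
    norm_tag <- "cp10k_log1p"
  } else {
    x <- m
    if (is.null(rownames(x))) stop("matrix must have gene rownames",
                                   call. = FALSE)
    norm_tag <- "pre-normalized"
  }
  gene_set <- unique(as.character(gene_set))
  present <- intersect(gene_set, rownames(x))
  missing <- setdiff(gene_set, rownames(x))
  if (!length(present))
    stop("no gene of the set is present; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(missing))
    warning("dropping absent gene(s): ", paste(missing, collapse = ", "),
            call. = FALSE)
  if (n_bins > nrow(x))
    stop("n_bins (", n_bins, ") exceeds gene count (", nrow(x), ")",
         call. = FALSE)

  # Expression bins: order by (mean, symbol), equal-size cut.
  mu <- Matrix::rowMeans(x)
  ord <- order(mu, rownames(x))
  bin_of <- integer(nrow(x))
  bin_of[ord] <- ceiling(seq_along(ord) * n_bins / nrow(x))
  names(bin_of) <- rownames(x)
  bin_members <- split(rownames(x)[ord], bin_of[ord])  # (mean, symbol) order

  set_sorted <- sort(present)
  draw_seed <- derive_seed(seed, paste0("modscore:",
                                        paste(set_sorted, collapse = ",")))
  controls <- withr::with_seed(draw_seed, {
    lapply(stats::setNames(set_sorted, set_sorted), function(g) {
      pool <- bin_members[[as.character(bin_of[[g]])]]
      pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
    })
  })

  set_mean <- Matrix::colMeans(x[present, , drop = FALSE])
  pooled <- unlist(controls, use.names = FALSE)
  w <- table(pooled)
  ctrl_genes <- names(w)
  ctrl_mean <- as.numeric(
    (as.numeric(w) %*% x[ctrl_genes, , drop = FALSE]) / length(pooled))
  scores <- set_mean - ctrl_mean
  names(scores) <- colnames(x)

  structure(list(
    gene_set_id = gene_set_id %||% paste0("set_", length(set_sorted), "g"),
    scores = scores,
    params = list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed,
                  normalization = norm_tag, genes_used = set_sorted,
                  genes_missing = missing),
    controls = controls), class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("signature_result '%s': %d cells, median score %.4f\n",
              x$gene_set_id, length(x$scores), stats::median(x$scores)))
  invisible(x)
}

#' M1-to-M2 macrophage polarization score
#'
#' The M2 expression score subtracted from the M1 expression score, both
#' computed by [module_score()] under the same seed policy (draws keyed by
#' each set's content). Higher values indicate M1 (pro-inflammatory)
#' polarization. Exactly antisymmetric under swapping the two sets, and
#' identically zero when they coincide.
#'
#' @param m matrix input as in [module_score()].
#' @param m1_set,m2_set marker gene vectors
#'   (defaults from [default_signature_sets()]).
#' @param n_bins,n_ctrl,seed scoring parameters, applied to both calls.
#' @return A \code{signature_result} with id \code{"M1_to_M2"}.
#' @export
m1_to_m2 <- function(m, m1_set = default_signature_sets()$M1,
                     m2_set = default_signature_sets()$M2,
                     n_bins = 24, n_ctrl = 100, seed = 0) {
  s1 <- module_score(m, m1_set, n_bins, n_ctrl, seed, gene_set_id = "M1")
  s2 <- module_score(m, m2_set, n_bins, n_ctrl, seed, gene_set_id = "M2")
  structure(list(
    gene_set_id = "M1_to_M2",
    scores = s1$scores - s2$scores,
    params = list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed,
                  normalization = s1$params$normalization,
                  m1_genes = s1$params$genes_used,
                  m2_genes = s2$params$genes_used),
    controls = list(M1 = s1$controls, M2 = s2$controls)),
    class = "signature_result")
}

#' Per-stratum two-group score contrast
#'
#' One Wilcoxon rank-sum test per (tissue) stratum comparing the two groups'
#' per-cell scores, Holm-adjusted across strata, with the direction of the
#' treated-minus-reference median difference. Strata with fewer than 2 cells
#' in either arm are reported as not testable (NA p, excluded from the
#' adjustment).
#'
#' @param scores a \code{signature_result} or a named numeric vector keyed
#'   by barcode.
#' @param meta data.frame with \code{barcode}, \code{tissue}, \code{group}.
#' @param groups length-2 character: reference and treated group labels.
#' @param strata strata to test (default: tissues present, in cohort order).
#' @return data.table (tissue, n_ref, n_trt, median_diff, statistic, p,
#'   p_adj, stars, testable).
#' @export
score_group_contrast <- function(scores, meta,
                                 groups = c("normal", "sephin1"),
                                 strata = NULL) {
  sc <- if (inherits(scores, "signature_result")) scores$scores else scores
  dt <- data.table::as.data.table(meta)[, c("barcode", "tissue", "group")]
  dt <- dt[dt$barcode %in% names(sc) & dt$group %in% groups]
  dt[, "score" := sc[dt$barcode]]
  strata <- strata %||% intersect(COHORT_TISSUES, unique(dt$tissue))

  rows <- lapply(strata, function(ti) {
    x <- dt$score[dt$tissue == ti & dt$group == groups[1]]
    y <- dt$score[dt$tissue == ti & dt$group == groups[2]]
    if (length(x) < 2 || length(y) < 2)
      return(data.table(tissue = ti, n_ref = length(x), n_trt = length(y),
                        median_diff = NA_real_, statistic = NA_real_,
                        p = NA_real_, testable = FALSE))
    wt <- wilcoxon_rank_sum(x, y)
    data.table(tissue = ti, n_ref = length(x), n_trt = length(y),
               median_diff = stats::median(y) - stats::median(x),
               statistic = wt$statistic, p = wt$p, testable = TRUE)
  })
  out <- data.table::rbindlist(rows)
  out[, "p_adj" := NA_real_]
  if (any(out$testable))
    out[out$testable, "p_adj" := holm_adjust(out$p[out$testable])]
  out[, "stars" := vapply(out$p_adj, function(p)
    if (is.na(p)) NA_character_ else stars(p), character(1))]
  out[]
}
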