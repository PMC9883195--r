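# Synthetic paired GEX+VDJ cohort generator with planted, recoverable ground
# truth. The stated world mirrors the study design it emulates: two arms
# (normal / sephin1), three sample types (blood day 0, blood day 15, tumor
# day 15), two replicate samples per arm per tissue; negative-binomial counts
# with marker elevation; group/tissue-dependent signature shifts; skewed
# clone sizes whose skew is damped in the treated arm; and a planted rate of
# T-cell-to-macrophage TCR transfer, higher in tumor than blood.

COHORT_GROUPS <- c("normal", "sephin1")
COHORT_TISSUES <- c("blood_d0", "blood_d15", "tumor_d15")
TCR_CELL_TYPES <- c("Cd4_T", "Cd8_T", "NKT")

default_cell_type_proportions <- function(tissues = COHORT_TISSUES) {
  blood <- c(Cd4_T = 0.22, Cd8_T = 0.18, NK = 0.08, NKT = 0.05,
             B = 0.22, Macrophage = 0.25)
  tumor <- c(Cd4_T = 0.15, Cd8_T = 0.22, NK = 0.08, NKT = 0.05,
             B = 0.05, Macrophage = 0.45)
  props <- lapply(stats::setNames(tissues, tissues), function(ti) {
    v <- if (grepl("^tumor", ti)) tumor else blood
    list(normal = v, sephin1 = v)
  })
  props
}

default_sig_shifts <- function() {
  list(
    list(set = "M2", group = "sephin1", tissues = c("blood_d15", "tumor_d15"),
         cell_types = "Macrophage", lfc = 0.5),
    list(set = "cytotoxicity", group = "sephin1",
         tissues = c("blood_d15", "tumor_d15"),
         cell_types = c("Cd8_T", "NK", "NKT"), lfc = -0.5)
  )
}

#' Cohort simulation configuration
#'
#' Defaults state the emulated world: 2 samples per arm per tissue (the
#' study's 12-sample design at desk scale), 1000 cells/sample, a 2000-gene
#' universe, negative-binomial counts (per-gene baseline means log-normal
#' around \code{nb_mean}, dispersion \code{nb_dispersion}), 5-fold marker
#' elevation, +0.5 log-fold M2 shift and -0.5 cytotoxicity shift in the
#' treated arm at day 15, power-law clone sizes (exponent 2) damped by
#' \code{expansion_damp = 0.3} in the treated arm, TCR transfer rates
#' 0.137 (tumor) / 0.005 (blood) with a 0.8 Cd8-donor mix.
#'
#' @param n_samples_per_arm replicate samples per (group, tissue).
#' @param tissues subset of \code{blood_d0}, \code{blood_d15}, \code{tumor_d15}.
#' @param n_cells_per_sample cells per sample.
#' @param n_genes gene-universe size (see [build_gene_universe()]).
#' @param cell_type_proportions nested list \code{[[tissue]][[group]]} of
#'   probability vectors over cell types (default [default_cell_type_proportions()]).
#' @param nb_mean baseline per-gene mean UMI scale.
#' @param nb_dispersion negative-binomial size parameter.
#' @param marker_fold mean multiplier for a type's markers in that type (>= 1).
#' @param sig_shift list of planted shifts, each
#'   \code{list(set|genes, group, tissues, cell_types, lfc)}; gene means are
#'   scaled by \code{exp(lfc)} in matching cells.
#' @param clone_dist \code{list(type = "power_law", exponent = 2)},
#'   \code{list(type = "log_normal", meanlog, sdlog)}, or
#'   \code{list(type = "degenerate", size)}.
#' @param expansion_damp skew damping factor in \code{(0, 1]} applied to the
#'   sephin1 arm's clone-size draw.
#' @param trog_rate named per-tissue probability that a macrophage carries a
#'   T-cell clonotype.
#' @param trog_donor_mix probability the donor T cell is Cd8 (vs Cd4).
#' @param seed master seed; one RNG stream per sample is derived from
#'   (seed, sample_id).
#' @return A validated \code{cohort_config} list.
#' @export
cohort_config <- function(n_samples_per_arm = 2,
                          tissues = COHORT_TISSUES,
                          n_cells_per_sample = 1000,
                          n_genes = 2000,
                          cell_type_proportions = NULL,
                          nb_mean = 0.3,
                          nb_dispersion = 2,
                          marker_fold = 5,
                          sig_shift = default_sig_shifts(),
                          clone_dist = list(type = "power_law", exponent = 2),
                          expansion_damp = 0.3,
                          trog_rate = c(blood_d0 = 0.005, blood_d15 = 0.005,
                                        tumor_d15 = 0.137),
                          trog_donor_mix = 0.8,
                          seed = 42) {
  tissues <- match.arg(tissues, COHORT_TISSUES, several.ok = TRUE)
  props <- cell_type_proportions %||% default_cell_type_proportions(tissues)
  for (ti in tissues) for (g in COHORT_GROUPS) {
    v <- props[[ti]][[g]]
    if (is.null(v))
      stop("config error: cell_type_proportions missing tissue '", ti,
           "' group '", g, "'", call. = FALSE)
    if (abs(sum(v) - 1) > 1e-9)
      stop("config error: proportions for ", ti, "/", g, " sum to ", sum(v),
           call. = FALSE)
    if (any(v < 0)) stop("config error: negative proportion", call. = FALSE)
  }
  if (any(trog_rate < 0 | trog_rate > 1) ||
      trog_donor_mix < 0 || trog_donor_mix > 1)
    stop("config error: rates must lie in [0, 1]", call. = FALSE)
  if (any(!tissues %in% names(trog_rate)))
    stop("config error: trog_rate missing tissue(s): ",
         paste(setdiff(tissues, names(trog_rate)), collapse = ", "),
         call. = FALSE)
  if (expansion_damp <= 0 || expansion_damp > 1)
    stop("config error: expansion_damp must lie in (0, 1]", call. = FALSE)
  stopifnot(n_samples_per_arm >= 1, n_cells_per_sample >= 1,
            nb_mean > 0, nb_dispersion > 0, marker_fold >= 1)
  structure(list(
    n_samples_per_arm = as.integer(n_samples_per_arm), tissues = tissues,
    n_cells_per_sample = as.integer(n_cells_per_sample),
    n_genes = as.integer(n_genes), cell_type_proportions = props,
    nb_mean = nb_mean, nb_dispersion = nb_dispersion,
    marker_fold = marker_fold, sig_shift = sig_shift,
    clone_dist = clone_dist, expansion_damp = expansion_damp,
    trog_rate = trog_rate, trog_donor_mix = trog_donor_mix,
    seed = as.integer(seed)), class = "cohort_config")
}

#' Draw a clone-size partition of a repertoire
#'
#' Sizes are drawn i.i.d. from \code{dist} until they cover \code{n_cells};
#' the final clone is truncated so sizes sum exactly to \code{n_cells}.
#' \code{damp < 1} damps the skew (power law: exponent divided by
#' \code{damp}; log-normal: sdlog multiplied by \code{damp}), strictly
#' reducing the expected share of the largest clone.
#'
#' @param n_cells number of TCR-bearing cells to partition (> 0).
#' @param dist distribution spec, see [cohort_config()].
#' @param damp skew damping in (0, 1].
#' @param seed integer seed.
#' @return Integer vector of clone sizes summing to \code{n_cells}.
#' @export
generate_clone_sizes <- function(n_cells,
                                 dist = list(type = "power_law", exponent = 2),
                                 damp = 1, seed = 1) {
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 1)
    stop("n_cells must be a positive integer", call. = FALSE)
  if (damp <= 0 || damp > 1) stop("damp must lie in (0, 1]", call. = FALSE)
  n_cells <- as.integer(n_cells)
  draw <- switch(dist$type %||% "power_law",
    power_law = {
      alpha <- (dist$exponent %||% 2) / damp
      support <- seq_len(n_cells)
      prob <- support^(-alpha)
      function(k) sample(support, k, replace = TRUE, prob = prob)
    },
    log_normal = {
      function(k) pmax(1L, as.integer(round(rlnorm(
        k, dist$meanlog %||% 0, (dist$sdlog %||% 1) * damp))))
    },
    degenerate = {
      sz <- as.integer(dist$size %||% 1)
      function(k) rep(sz, k)
    },
    stop("config error: unknown clone distribution type '", dist$type, "'",
         call. = FALSE)
  )
  withr::with_seed(seed, {
    sizes <- integer(0)
    total <- 0L
    while (total < n_cells) {
      new <- draw(max(16L, ceiling((n_cells - total) / 2)))
      sizes <- c(sizes, new)
      total <- total + sum(new)
    }
    cum <- cumsum(sizes)
    last <- which(cum >= n_cells)[1]
    sizes <- sizes[seq_len(last)]
    sizes[last] <- sizes[last] - (cum[last] - n_cells)
    as.integer(sizes[sizes > 0])
  })
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
# Fixed one-codon-per-amino-acid back-translation; keeps cdr3_nt length
# divisible by 3 and deterministic given cdr3_aa.
AA_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

random_cdr3 <- function(n) {
  lens <- sample(10:15, n, replace = TRUE)
  aa <- vapply(lens, function(l)
    paste0("C", paste(sample(AA20, l - 2, replace = TRUE), collapse = ""), "F"),
    character(1))
  nt <- vapply(strsplit(aa, ""), function(ch)
    paste(AA_CODON[ch], collapse = ""), character(1))
  list(aa = aa, nt = nt)
}

random_barcodes <- function(n) {
  repeat {
    bc <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 16, replace = TRUE), collapse = ""),
      character(1))
    if (!anyDuplicated(bc)) return(paste0(bc, "-1"))
  }
}

# One fully specified clonotype: a TRA and a TRB chain.
make_clonotypes <- function(n) {
  a <- random_cdr3(n); b <- random_cdr3(n)
  data.table::data.table(
    clone = seq_len(n),
    tra_v = paste0("TRAV", sample(1:20, n, replace = TRUE)),
    tra_j = paste0("TRAJ", sample(1:30, n, replace = TRUE)),
    tra_aa = a$aa, tra_nt = a$nt,
    trb_v = paste0("TRBV", sample(1:20, n, replace = TRUE)),
    trb_d = paste0("TRBD", sample(1:2, n, replace = TRUE)),
    trb_j = paste0("TRBJ", sample(1:12, n, replace = TRUE)),
    trb_aa = b$aa, trb_nt = b$nt)
}

contig_rows_for <- function(barcodes, ct, clonotype_ids) {
  n <- length(barcodes)
  umis_a <- rpois(n, 3) + 1L
  umis_b <- rpois(n, 5) + 1L
  mk <- function(chain, v, d, j, c_gene, aa, nt, umis) data.table::data.table(
    barcode = barcodes, is_cell = TRUE, high_confidence = TRUE, chain = chain,
    v_gene = v, d_gene = d, j_gene = j, c_gene = c_gene,
    cdr3 = aa, cdr3_nt = nt,
    reads = umis * sample(20:60, n, replace = TRUE), umis = umis,
    productive = TRUE, raw_clonotype_id = paste0("clonotype", clonotype_ids))
  rbind(
    mk("TRA", ct$tra_v, "", ct$tra_j, "TRAC", ct$tra_aa, ct$tra_nt, umis_a),
    mk("TRB", ct$trb_v, ct$trb_d, ct$trb_j, "TRBC1", ct$trb_aa, ct$trb_nt,
       umis_b))
}

#' Generate a paired GEX + VDJ cohort with planted ground truth
#'
#' Deterministic given \code{cfg$seed}; each sample draws from its own RNG
#' stream derived from (seed, sample_id) so outputs do not depend on sample
#' order. Counts are negative-binomial with marker elevation and planted
#' signature shifts; T/NKT cells receive clonotypes drawn per compartment
#' from the configured clone-size law (treated arm damped); a per-tissue
#' fraction of macrophages receives the full contig set of a donor T cell
#' chosen uniformly within the donor compartment (clone-size proportional at
#' the clonotype level), Cd8 vs Cd4 by \code{trog_donor_mix}.
#'
#' @param cfg a [cohort_config()].
#' @return List with \code{samples} (named list of
#'   \code{list(matrix = ExpressionMatrix, contigs = data.table)}),
#'   \code{cell_meta} (data.table: barcode, sample_id, group, tissue,
#'   true_type, clonotype_key, donor_compartment), and \code{manifest}
#'   (per-cell truth, realized clone-size tables, realized per-tissue
#'   trogocytosis rates, configured shifts).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  genes <- build_gene_universe(cfg$n_genes)
  markers <- default_marker_sets()
  sigs <- default_signature_sets()
  base_means <- with_stream(cfg$seed, "gene_means", {
    mu <- rlnorm(length(genes), meanlog = log(cfg$nb_mean), sdlog = 1.2)
    names(mu) <- genes
    # curated marker/signature genes are robustly detected in real data
    # (canonical markers sit well above the transcriptome-wide median):
    # pin them at a mean of 1 UMI so fold changes are interpretable
    curated <- intersect(unique(c(unlist(markers), unlist(sigs))), genes)
    mu[curated] <- 1
    mu[intersect(MITO_GENES, genes)] <-
      mu[intersect(MITO_GENES, genes)] * 15  # realistic mito fraction
    mu
  })

  shift_genes <- lapply(cfg$sig_shift, function(s)
    s$genes %||% sigs[[s$set]] %||%
      stop("config error: unknown shift set '", s$set, "'", call. = FALSE))

  samples <- list()
  meta_list <- list()
  clone_tables <- list()
  trog_tally <- data.table::data.table(tissue = character(), n_mac = integer(),
                                       n_trog = integer())

  for (group in COHORT_GROUPS) for (tissue in cfg$tissues)
    for (rep_i in seq_len(cfg$n_samples_per_arm)) {
      sample_id <- sprintf("%s_%s_s%d", group, tissue, rep_i)
      res <- with_stream(cfg$seed, sample_id,
        simulate_sample(cfg, sample_id, group, tissue, genes, base_means,
                        markers, shift_genes))
      samples[[sample_id]] <- res$sample
      meta_list[[sample_id]] <- res$meta
      clone_tables[[sample_id]] <- res$clone_sizes
      trog_tally <- rbind(trog_tally, data.table::data.table(
        tissue = tissue, n_mac = res$n_mac, n_trog = res$n_trog))
    }

  cell_meta <- data.table::rbindlist(meta_list)
  realized <- trog_tally[, list(n_mac = sum(n_mac), n_trog = sum(n_trog)),
                         by = "tissue"]
  realized[, rate := n_trog / pmax(1L, n_mac)]
  list(
    samples = samples,
    cell_meta = cell_meta,
    manifest = list(cells = cell_meta, clone_sizes = clone_tables,
                    realized_trog_rate = realized,
                    sig_shift = cfg$sig_shift, seed = cfg$seed))
}

simulate_sample <- function(cfg, sample_id, group, tissue, genes, base_means,
                            markers, shift_genes) {
  n <- cfg$n_cells_per_sample
  props <- cfg$cell_type_proportions[[tissue]][[group]]
  types <- sample(names(props), n, replace = TRUE, prob = props)
  barcodes <- random_barcodes(n)

  # Per-type mean vectors: marker elevation + planted shifts.
  counts <- matrix(0L, nrow = length(genes), ncol = n)
  for (ty in unique(types)) {
    idx <- which(types == ty)
    mu <- base_means
    mk <- intersect(markers[[ty]] %||% character(0), genes)
    mu[mk] <- mu[mk] * cfg$marker_fold
    for (k in seq_along(cfg$sig_shift)) {
      s <- cfg$sig_shift[[k]]
      if (!identical(s$group, group)) next
      if (!is.null(s$tissues) && !tissue %in% s$tissues) next
      if (!is.null(s$cell_types) && !ty %in% s$cell_types) next
      sg <- intersect(shift_genes[[k]], genes)
      mu[sg] <- mu[sg] * exp(s$lfc)
    }
    counts[, idx] <- rnbinom(length(genes) * length(idx), mu = mu,
                             size = cfg$nb_dispersion)
  }
  m <- ExpressionMatrix(counts, genes, barcodes)

  # Clonotypes per TCR-bearing compartment.
  damp <- if (group == "sephin1") cfg$expansion_damp else 1
  contigs <- list()
  clonotype_key <- rep(NA_character_, n)
  compartment_of_clone <- list()
  clone_sizes_out <- list()
  clone_offset <- 0L
  for (ty in intersect(TCR_CELL_TYPES, unique(types))) {
    idx <- which(types == ty)
    sizes <- generate_clone_sizes(length(idx), cfg$clone_dist, damp,
                                  derive_seed(cfg$seed,
                                              paste(sample_id, ty, "clones")))
    ct <- make_clonotypes(length(sizes))
    ct$clone <- ct$clone + clone_offset
    clone_offset <- clone_offset + nrow(ct)
    assign <- rep(seq_len(nrow(ct)), sizes)
    cells_ct <- ct[assign]
    contigs[[ty]] <- contig_rows_for(barcodes[idx], cells_ct, cells_ct$clone)
    keys <- clonotype_key_from_pair(cells_ct)
    clonotype_key[idx] <- keys
    compartment_of_clone[[ty]] <- unique(clonotype_key_from_pair(ct))
    clone_sizes_out[[ty]] <- sizes
  }

  # Trogocytosis: macrophages inherit a donor T cell's full contig set.
  donor_compartment <- rep("none", n)
  mac_idx <- which(types == "Macrophage")
  n_trog <- 0L
  if (length(mac_idx)) {
    rate <- cfg$trog_rate[[tissue]]
    is_trog <- runif(length(mac_idx)) < rate
    all_contigs <- data.table::rbindlist(contigs)
    bc_rows <- split(seq_len(nrow(all_contigs)), all_contigs$barcode)
    for (mi in mac_idx[is_trog]) {
      want_cd8 <- runif(1) < cfg$trog_donor_mix
      pool_ty <- if (want_cd8 && any(types == "Cd8_T")) "Cd8_T"
                 else if (any(types == "Cd4_T")) "Cd4_T"
                 else if (any(types == "Cd8_T")) "Cd8_T" else NULL
      if (is.null(pool_ty)) next
      donor <- sample(which(types == pool_ty), 1)
      rows <- all_contigs[bc_rows[[barcodes[donor]]]]
      rows$barcode <- barcodes[mi]
      contigs[[length(contigs) + 1L]] <- rows
      clonotype_key[mi] <- clonotype_key[donor]
      donor_compartment[mi] <- sub("_T$", "", pool_ty)
      n_trog <- n_trog + 1L
    }
  }
  contig_dt <- if (length(contigs)) data.table::rbindlist(contigs) else
    data.table::data.table()
  if (nrow(contig_dt)) {
    data.table::setorderv(contig_dt, c("barcode", "chain", "cdr3_nt"))
    contig_dt[, cdr3_aa := cdr3]
  }

  list(
    sample = list(matrix = m, contigs = contig_dt),
    meta = data.table::data.table(
      barcode = barcodes, sample_id = sample_id, group = group,
      tissue = tissue, true_type = types, clonotype_key = clonotype_key,
      donor_compartment = donor_compartment),
    clone_sizes = clone_sizes_out,
    n_mac = length(mac_idx), n_trog = n_trog)
}

# Ground-truth clonotype key for a TRA+TRB pair, matching call_clonotypes'
# "nt+gene" convention: sorted "chain:v:j:cdr3_nt" joined by ";".
clonotype_key_from_pair <- function(ct) {
  a <- paste("TRA", ct$tra_v, ct$tra_j, ct$tra_nt, sep = ":")
  b <- paste("TRB", ct$trb_v, ct$trb_j, ct$trb_nt, sep = ":")
  ifelse(a <= b, paste(a, b, sep = ";"), paste(b, a, sep = ";"))
}

#' Write a cohort to disk in the pipeline's input formats
#'
#' Per sample: \code{<dir>/<sample>/matrix/} (MatrixMarket + sidecars) and
#' \code{<dir>/<sample>/filtered_contig_annotations.csv}; plus
#' \code{cell_metadata.tsv} and \code{manifest.json} at the top level.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$samples)) {
    sdir <- file.path(dir, sid)
    write_matrix(cohort$samples[[sid]]$matrix, file.path(sdir, "matrix"))
    write_contigs(cohort$samples[[sid]]$contigs,
                  file.path(sdir, "filtered_contig_annotations.csv"))
  }
  utils::write.table(cohort$cell_meta, file.path(dir, "cell_metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(samples = names(cohort$samples),
         realized_trog_rate = cohort$manifest$realized_trog_rate,
         seed = cohort$manifest$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a directory-of-samples cohort written by [write_cohort()]
#'
#' Also accepts hand-assembled directories following the same layout.
#'
#' @param dir cohort directory.
#' @return List with \code{samples} and \code{cell_meta} as in
#'   [generate_cohort()] (no manifest).
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "cell_metadata.tsv")
  if (!file.exists(meta_path))
    stop("missing cell_metadata.tsv in ", dir, call. = FALSE)
  cell_meta <- data.table::as.data.table(
    utils::read.delim(meta_path, stringsAsFactors = FALSE))
  samples <- list()
  for (sid in unique(cell_meta$sample_id)) {
    sdir <- file.path(dir, sid)
    contig_path <- file.path(sdir, "filtered_contig_annotations.csv")
    if (!file.exists(contig_path) && !file.exists(paste0(contig_path, ".gz")))
      stop("sample '", sid, "': missing contig table at ", contig_path,
           call. = FALSE)
    if (!file.exists(contig_path)) contig_path <- paste0(contig_path, ".gz")
    samples[[sid]] <- list(matrix = read_matrix(file.path(sdir, "matrix")),
                           contigs = read_contigs(contig_path))
  }
  list(samples = samples, cell_meta = cell_meta)
}
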