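# End-to-end orchestration: simulate/ingest -> QC -> annotate -> repertoire
# -> signatures -> trogocytosis -> statistics, with stage-granular logging
# (counts in/out per filter) and a JSON run manifest. Deterministic given
# the configured seeds; re-running a config reproduces every numeric output.

#' Pipeline run configuration
#'
#' @param mode \code{"synthetic"} (generate a cohort from \code{cohort}) or
#'   \code{"directory"} (read a [write_cohort()]-layout directory from
#'   \code{input_dir}).
#' @param cohort a [cohort_config()] (synthetic mode).
#' @param input_dir cohort directory (directory mode).
#' @param out_dir where the report bundle is written.
#' @param use_true_types use manifest/metadata cell types instead of
#'   marker-score annotation (synthetic mode only; directory mode uses a
#'   \code{cell_type} metadata column when present).
#' @param marker_sets marker sets for annotation.
#' @param signature_sets named gene-set list with \code{cytotoxicity},
#'   \code{M1}, \code{M2} entries.
#' @param clonotype_strategy \code{"nt+gene"} or \code{"aa"}.
#' @param thresholds a [bin_thresholds()].
#' @param qc named list of [qc_filter()] arguments.
#' @param pooled_scoring score signatures on the sample-pooled matrix
#'   (scores comparable across arms) instead of per sample.
#' @param seed seed for signature control draws.
#' @return A \code{run_config} list.
#' @export
run_config <- function(mode = c("synthetic", "directory"),
                       cohort = cohort_config(), input_dir = NULL,
                       out_dir = tempfile("clonomac_run_"),
                       use_true_types = FALSE,
                       marker_sets = default_marker_sets(),
                       signature_sets = default_signature_sets(),
                       clonotype_strategy = c("nt+gene", "aa"),
                       thresholds = bin_thresholds(),
                       qc = list(), pooled_scoring = FALSE, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "directory" && (is.null(input_dir) || !dir.exists(input_dir)))
    stop("config error: directory mode needs an existing input_dir",
         call. = FALSE)
  structure(list(mode = mode, cohort = cohort, input_dir = input_dir,
                 out_dir = out_dir, use_true_types = use_true_types,
                 marker_sets = marker_sets, signature_sets = signature_sets,
                 clonotype_strategy = match.arg(clonotype_strategy),
                 thresholds = thresholds, qc = qc,
                 pooled_scoring = pooled_scoring, seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, log, code) {
  res <- tryCatch(code, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  res
}

#' Run the full pipeline
#'
#' Emits, under \code{cfg$out_dir}: \code{composition.csv} (cell-type
#' percentages with per-tissue chi-squared), \code{clonotype_bins_*.csv}
#' (clonotype- and cell-level expansion-bin panels with chi-squared),
#' \code{clonotypes.csv}, \code{signature_contrasts.csv} (Wilcoxon + Holm +
#' stars), \code{tcr_mac_report.csv} / \code{tcr_mac_shares.csv} /
#' \code{tcr_mac_bins.csv}, and \code{run_manifest.json} (parameters, seeds,
#' per-stage QC ledger). Any stage failure halts with a stage-named error
#' and leaves a \code{FAILED} marker file in the output directory.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with every in-memory artifact
#'   (\code{cohort}, \code{meta}, \code{tables}, \code{composition},
#'   \code{bin_comp}, \code{signatures}, \code{trog}, \code{manifest}).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  on_fail <- function(e) {
    writeLines(conditionMessage(e), file.path(cfg$out_dir, "FAILED"))
    stop(e)
  }
  withCallingHandlers(run_pipeline_impl(cfg), error = on_fail)
}

run_pipeline_impl <- function(cfg) {
  log <- list()

  cohort <- stage("input", log, {
    if (cfg$mode == "synthetic") generate_cohort(cfg$cohort)
    else read_cohort(cfg$input_dir)
  })
  meta <- data.table::as.data.table(cohort$cell_meta)

  qc_log <- list()
  filtered <- stage("qc", log, {
    lapply(cohort$samples, function(s) {
      f <- do.call(qc_filter, c(list(s$matrix), cfg$qc))
      qc_log[[length(qc_log) + 1L]] <<- attr(f, "qc_log")
      f
    })
  })
  names(qc_log) <- names(filtered)
  keep <- data.table::rbindlist(lapply(names(filtered), function(sid)
    data.table(sample_id = sid, barcode = filtered[[sid]]$barcodes)))
  meta <- merge(meta, keep, by = c("sample_id", "barcode"), sort = FALSE)

  meta <- stage("annotate", log, {
    if (cfg$use_true_types && "true_type" %in% names(meta)) {
      meta[, "cell_type" := meta$true_type]
      meta
    } else if (!cfg$use_true_types && "cell_type" %in% names(meta)) {
      meta  # externally supplied labels (directory mode)
    } else {
      key <- data.table::rbindlist(lapply(names(filtered), function(sid) {
        labels <- assign_cell_types(filtered[[sid]], cfg$marker_sets)
        data.table(sample_id = sid, barcode = filtered[[sid]]$barcodes,
                   cell_type = unname(labels))
      }))
      merge(meta, key, by = c("sample_id", "barcode"), sort = FALSE)
    }
  })

  composition <- stage("composition", log, {
    comp <- composition_table(meta)
    tests <- composition_tests(meta)
    list(table = comp, tests = tests)
  })

  rep_res <- stage("repertoire", log, {
    tables <- lapply(names(cohort$samples), function(sid)
      bin_clonotypes(call_clonotypes(cohort$samples[[sid]]$contigs,
                                     cfg$clonotype_strategy, sid),
                     cfg$thresholds))
    names(tables) <- names(cohort$samples)
    bins <- data.table::rbindlist(lapply(names(tables), function(sid) {
      sub <- meta[meta$sample_id == sid]
      cbind(sample_id = sid, cell_bin_labels(tables[[sid]], sub))
    }))
    comp <- bin_composition(tables, meta)
    tests <- bin_composition_tests(comp$cell_level)
    list(tables = tables, bins = bins, composition = comp, tests = tests)
  })

  signatures <- stage("signatures", log, {
    if (cfg$pooled_scoring) {
      # one shared expression-bin layout; keys prefixed to stay unique
      pooled <- pool_matrices(filtered, prefix = TRUE)
      score_all <- function(score_fun) score_fun(pooled)$scores
      key_of <- function(d) paste0(d$sample_id, "_", d$barcode)
    } else {
      score_all <- function(score_fun) {
        out <- lapply(names(filtered), function(sid)
          score_fun(filtered[[sid]]))
        stats::setNames(unlist(lapply(out, `[[`, "scores")),
                        unlist(lapply(out, function(o) names(o$scores))))
      }
      key_of <- function(d) d$barcode
    }
    cyt <- score_all(function(m) module_score(
      m, cfg$signature_sets$cytotoxicity, seed = cfg$seed,
      gene_set_id = "cytotoxicity"))
    m12 <- score_all(function(m) m1_to_m2(
      m, cfg$signature_sets$M1, cfg$signature_sets$M2, seed = cfg$seed))
    contrast_meta <- function(d) {
      d <- data.table::copy(d)
      d[, "barcode" := key_of(d)]
      d
    }
    cd8 <- contrast_meta(meta[meta$cell_type == "Cd8_T"])
    mac <- contrast_meta(meta[meta$cell_type == "Macrophage"])
    contrasts <- rbind(
      cbind(signature = "cytotoxicity_Cd8_T",
            score_group_contrast(cyt, cd8)),
      cbind(signature = "M1_to_M2_Macrophage",
            score_group_contrast(m12, mac)))
    list(cytotoxicity = cyt, m1_to_m2 = m12, contrasts = contrasts)
  })

  trog <- stage("trogocytosis", log, {
    flags <- match_barcodes(meta, rep_res$tables)
    frac <- tcr_mac_fraction(meta, flags)
    shares <- suppressWarnings(
      shared_clonotype_fractions(meta, flags, rep_res$tables))
    mac_bins <- suppressWarnings(
      tcr_mac_bin_distribution(meta, flags, rep_res$bins))
    list(flags = flags, fraction = frac, shares = shares,
         mac_bins = mac_bins)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("clonomac")),
    mode = cfg$mode,
    seed = cfg$seed,
    cohort_seed = if (cfg$mode == "synthetic") cfg$cohort$seed else NULL,
    clonotype_strategy = cfg$clonotype_strategy,
    qc = qc_log,
    n_cells_final = nrow(meta))

  stage("write", log, {
    out <- cfg$out_dir
    wcsv <- function(x, f) utils::write.csv(as.data.frame(x),
                                            file.path(out, f),
                                            row.names = FALSE)
    wcsv(composition$table, "composition.csv")
    wcsv(composition$tests, "composition_tests.csv")
    wcsv(rep_res$composition$clonotype_level, "clonotype_bins_clonotype.csv")
    wcsv(rep_res$composition$cell_level, "clonotype_bins_cell.csv")
    wcsv(rep_res$tests, "clonotype_bin_tests.csv")
    clo <- data.table::rbindlist(lapply(rep_res$tables, function(t)
      if (nrow(t$clones)) cbind(sample_id = t$sample_id, t$clones) else NULL))
    wcsv(clo, "clonotypes.csv")
    wcsv(signatures$contrasts, "signature_contrasts.csv")
    wcsv(trog$fraction, "tcr_mac_report.csv")
    wcsv(trog$shares, "tcr_mac_shares.csv")
    wcsv(trog$mac_bins, "tcr_mac_bins.csv")
    jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  })

  invisible(list(cohort = cohort, meta = meta, tables = rep_res$tables,
                 composition = composition, bin_comp = rep_res$composition,
                 bins = rep_res$bins, signatures = signatures, trog = trog,
                 manifest = manifest))
}

# Per-tissue chi-squared of cell-type counts across groups.
composition_tests <- function(meta) {
  rows <- lapply(unique(meta$tissue), function(ti) {
    tab <- table(meta$cell_type[meta$tissue == ti],
                 meta$group[meta$tissue == ti])
    res <- tryCatch(chi_squared_composition(unclass(as.matrix(tab))),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.table(tissue = ti, statistic = NA_real_, df = NA_integer_,
                        p = NA_real_, stars = NA_character_))
    data.table(tissue = ti, statistic = res$statistic, df = res$df,
               p = res$p, stars = res$stars)
  })
  data.table::rbindlist(rows)
}

# Per-tissue chi-squared of cell-level bin counts across groups.
bin_composition_tests <- function(cell_level) {
  if (!nrow(cell_level)) return(data.table())
  rows <- lapply(unique(cell_level$tissue), function(ti) {
    sub <- cell_level[cell_level$tissue == ti]
    tab <- data.table::dcast(sub, bin ~ group, value.var = "count",
                             fill = 0L)
    mat <- as.matrix(tab[, -1, drop = FALSE])
    res <- tryCatch(chi_squared_composition(mat), error = function(e) NULL)
    if (is.null(res))
      return(data.table(tissue = ti, statistic = NA_real_, df = NA_integer_,
                        p = NA_real_, stars = NA_character_))
    data.table(tissue = ti, statistic = res$statistic, df = res$df,
               p = res$p, stars = res$stars)
  })
  data.table::rbindlist(rows)
}
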