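# Default marker and signature gene catalogues, and readers for user-supplied
# gene-set files (GMT or two-column TSV). The M1/M2 and cytotoxicity lists are
# documented stand-ins from the standard mouse polarization / effector-marker
# literature: they are config inputs, not hard-coded truth, and every scoring
# function accepts arbitrary replacement sets.

MITO_GENES <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp8", "mt-Atp6",
                "mt-Co3", "mt-Nd3", "mt-Nd4l", "mt-Nd4", "mt-Nd5", "mt-Nd6",
                "mt-Cytb")

#' Default immune-cell marker sets
#'
#' Classic mouse immune markers (Cd3d/Cd4/Cd8a/Klrb1c/Cd68/Csf1r/Adgre1 and
#' companions), ten per cell type. Lineage-shared markers (e.g. Cd3d across
#' T compartments) appear in several sets; each set keeps a majority of
#' exclusive markers so argmax typing is well posed.
#'
#' @return Named list of character vectors, one per cell type.
#' @export
default_marker_sets <- function() {
  list(
    Cd4_T      = c("Cd3d", "Cd3e", "Cd4", "Il7r", "Lef1", "Tcf7", "Ccr7",
                   "Cd28", "Icos", "Cd5"),
    Cd8_T      = c("Cd3d", "Cd3e", "Cd8a", "Cd8b1", "Gzmk", "Eomes", "Cd2",
                   "Lck", "Thy1", "Cd7"),
    NK         = c("Klrb1c", "Ncr1", "Prf1", "Gzmb", "Klrk1", "Klra8",
                   "Il2rb", "Txk", "Klrd1", "Nkg7"),
    NKT        = c("Cd3d", "Cd3e", "Klrb1c", "Zbtb16", "Cxcr6", "Slamf6",
                   "Il18r1", "Tbx21", "Rora", "Ccr2"),
    B          = c("Cd19", "Ms4a1", "Cd79a", "Cd79b", "Ighm", "Igkc",
                   "Ebf1", "Pax5", "Cd74", "Fcmr"),
    Macrophage = c("Cd68", "Csf1r", "Adgre1", "Lyz2", "Fcgr1", "Itgam",
                   "Mertk", "C1qa", "C1qb", "Apoe")
  )
}

#' Default signature gene sets
#'
#' \code{cytotoxicity}: effector/cytolysis genes used for the per-cell
#' cytotoxicity expression score. \code{M1} / \code{M2}: pro-inflammatory and
#' alternative macrophage polarization markers feeding the M1-to-M2 score.
#'
#' @return Named list with elements \code{cytotoxicity}, \code{M1}, \code{M2}.
#' @export
default_signature_sets <- function() {
  list(
    cytotoxicity = c("Gzma", "Gzmb", "Gzmk", "Prf1", "Ifng", "Nkg7",
                     "Klrg1", "Fasl", "Ctsw", "Klrd1"),
    M1 = c("Nos2", "Il1b", "Tnf", "Il6", "Cd86", "Cd80", "Cxcl9",
           "Cxcl10", "Il12b", "Tlr2"),
    M2 = c("Arg1", "Mrc1", "Chil3", "Retnla", "Il10", "Cd163", "Mgl2",
           "Ccl22", "Clec10a", "Tgfb1")
  )
}

#' Build the synthetic gene universe
#'
#' All marker, signature and mitochondrial genes plus anonymous filler genes
#' (\code{Gene0001}, ...) up to \code{n_genes}.
#'
#' @param n_genes total universe size (>= number of named genes).
#' @return Character vector of unique gene symbols.
#' @export
build_gene_universe <- function(n_genes = 2000) {
  named <- unique(c(unlist(default_marker_sets(), use.names = FALSE),
                    unlist(default_signature_sets(), use.names = FALSE),
                    MITO_GENES))
  if (n_genes < length(named))
    stop("n_genes must be >= ", length(named), " (the named genes)",
         call. = FALSE)
  c(named, sprintf("Gene%04d", seq_len(n_genes - length(named))))
}

#' Read gene sets from a GMT or two-column TSV file
#'
#' GMT: one set per line, \code{name<TAB>description<TAB>gene...}. TSV: two
#' columns \code{set<TAB>gene}, one gene per row, with or without a header.
#'
#' @param path file path; format inferred from the \code{.gmt} extension.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("gene-set file not found: ", path, call. = FALSE)
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    parts <- strsplit(readLines(path), "\t", fixed = TRUE)
    parts <- parts[vapply(parts, length, 0L) >= 3]
    stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                    vapply(parts, `[[`, "", 1L))
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (identical(tolower(df[1, 1]), "set")) df <- df[-1, , drop = FALSE]
    split(df[[2]], df[[1]])
  }
}
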