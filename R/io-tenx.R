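# Readers/writers for the two 10X-style artifact formats every other module
# consumes: MatrixMarket triplet + sidecar tables, and the
# filtered_contig_annotations.csv dialect. Gzip is sniffed by extension.

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

find_sidecar <- function(dir_path, stems) {
  for (stem in stems) for (ext in c("", ".gz")) {
    p <- file.path(dir_path, paste0(stem, ext))
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Read a MatrixMarket count matrix with 10X sidecar tables
#'
#' Expects \code{matrix.mtx}, \code{features.tsv} (or \code{genes.tsv}) and
#' \code{barcodes.tsv} in \code{dir_path}, each optionally gzipped. The
#' features table may carry one, two, or three tab-separated columns
#' (id, symbol, type); the symbol column is used when present. Coordinates in
#' the triplet file are 1-based per the MatrixMarket standard; absent entries
#' are zero.
#'
#' @param dir_path directory containing the three files.
#' @return An [ExpressionMatrix].
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(dir_path) {
  if (!dir.exists(dir_path))
    stop("matrix directory not found: ", dir_path, call. = FALSE)
  mtx <- find_sidecar(dir_path, "matrix.mtx")
  feat <- find_sidecar(dir_path, c("features.tsv", "genes.tsv"))
  bcs <- find_sidecar(dir_path, "barcodes.tsv")
  if (is.null(mtx)) stop("format error: missing matrix.mtx[.gz] in ", dir_path,
                         call. = FALSE)
  if (is.null(feat)) stop("format error: missing features.tsv[.gz]/genes.tsv[.gz] in ",
                          dir_path, call. = FALSE)
  if (is.null(bcs)) stop("format error: missing barcodes.tsv[.gz] in ", dir_path,
                         call. = FALSE)

  con <- open_maybe_gz(mtx); on.exit(close(con), add = TRUE)
  counts <- Matrix::readMM(con)

  read_tsv_col <- function(path) {
    con2 <- open_maybe_gz(path)
    on.exit(close(con2), add = TRUE)
    lines <- readLines(con2)
    lines <- lines[nzchar(lines)]
    strsplit(lines, "\t", fixed = TRUE)
  }
  feats <- read_tsv_col(feat)
  gene_ids <- vapply(feats, function(f) f[[min(2L, length(f))]], character(1))
  barcodes <- vapply(read_tsv_col(bcs), `[[`, character(1), 1L)

  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(barcodes))
    stop(sprintf(
      "dimension error: matrix is %d x %d but sidecars list %d genes, %d barcodes",
      nrow(counts), ncol(counts), length(gene_ids), length(barcodes)),
      call. = FALSE)
  ExpressionMatrix(counts, gene_ids, barcodes)
}

#' Write a count matrix as MatrixMarket triplet plus sidecars
#'
#' Emits \code{matrix.mtx}, \code{features.tsv} (id and symbol columns, both
#' the gene symbol), and \code{barcodes.tsv} into \code{dir_path}, readable
#' by [read_matrix()]. Refuses matrices violating the count invariants.
#'
#' @param m an [ExpressionMatrix].
#' @param dir_path output directory (created if absent).
#' @return \code{dir_path}, invisibly.
#' @export
write_matrix <- function(m, dir_path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (length(m$counts@x) && (any(m$counts@x < 0) || any(m$counts@x != round(m$counts@x))))
    stop("refusing to write: counts must be non-negative integers", call. = FALSE)
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir_path)) stop("cannot create ", dir_path, call. = FALSE)
  Matrix::writeMM(m$counts, file.path(dir_path, "matrix.mtx"))
  writeLines(paste(m$gene_ids, m$gene_ids, "Gene Expression", sep = "\t"),
             file.path(dir_path, "features.tsv"))
  writeLines(m$barcodes, file.path(dir_path, "barcodes.tsv"))
  invisible(dir_path)
}

CONTIG_COLUMNS <- c("barcode", "is_cell", "high_confidence", "chain",
                    "v_gene", "d_gene", "j_gene", "c_gene", "cdr3", "cdr3_nt",
                    "reads", "umis", "productive", "raw_clonotype_id")

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(trimws(as.character(x))) %in% c("true", "t", "1")
}

#' Read a 10X TCR contig annotation table
#'
#' Parses the \code{filtered_contig_annotations.csv} dialect (plain or
#' gzipped). Mandatory columns: barcode, is_cell, high_confidence, chain,
#' v_gene, d_gene, j_gene, c_gene, cdr3, cdr3_nt, reads, umis, productive,
#' raw_clonotype_id; extra columns are ignored. \code{"True"/"true"/"TRUE"}
#' all parse as flag true; empty gene fields stay empty strings.
#'
#' @param csv_path path to the contig CSV.
#' @return A \code{data.table} with one row per contig observation
#'   (\code{cdr3} is carried as \code{cdr3_aa} alias column as well).
#' @export
read_contigs <- function(csv_path) {
  if (!file.exists(csv_path))
    stop("format error: contig file not found: ", csv_path, call. = FALSE)
  con <- open_maybe_gz(csv_path)
  on.exit(close(con), add = TRUE)
  df <- utils::read.csv(con, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(CONTIG_COLUMNS, names(df))
  if (length(missing))
    stop("format error: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  dt <- data.table::as.data.table(df[, CONTIG_COLUMNS])
  for (fcol in c("is_cell", "high_confidence", "productive"))
    data.table::set(dt, j = fcol, value = parse_flag(dt[[fcol]]))
  for (icol in c("reads", "umis"))
    data.table::set(dt, j = icol, value = as.integer(dt[[icol]]))
  if (any(dt$reads < 0, na.rm = TRUE) || any(dt$umis < 0, na.rm = TRUE))
    stop("format error: negative reads/umis", call. = FALSE)
  dt[, "cdr3_aa" := dt$cdr3]
  dt[]
}

#' Write a contig table in the 10X CSV dialect
#'
#' @param contigs data.table/data.frame with the canonical contig columns.
#' @param csv_path output path.
#' @return \code{csv_path}, invisibly.
#' @export
write_contigs <- function(contigs, csv_path) {
  df <- as.data.frame(contigs)[, CONTIG_COLUMNS]
  for (fcol in c("is_cell", "high_confidence", "productive"))
    df[[fcol]] <- ifelse(df[[fcol]], "True", "False")
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}
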