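#' Gene-by-cell count matrix
#'
#' Lightweight container for a per-sample UMI count matrix: a sparse
#' genes x cells matrix of non-negative integers plus unique gene symbols
#' and unique cell barcodes (16-mer nucleotide, optional \code{"-1"} style
#' suffix retained verbatim).
#'
#' @param counts genes x cells matrix (dense or sparse) of non-negative
#'   integer UMI counts.
#' @param gene_ids character vector of unique gene symbols, one per row.
#' @param barcodes character vector of unique cell barcodes, one per column.
#' @return An object of class \code{ExpressionMatrix}: a list with elements
#'   \code{counts} (dgCMatrix with dimnames), \code{gene_ids}, \code{barcodes}.
#' @examples
#' m <- ExpressionMatrix(matrix(0:5, nrow = 2), c("g1", "g2"),
#'                       c("AAA-1", "CCC-1", "GGG-1"))
#' n_cells(m)
#' @export
ExpressionMatrix <- function(counts, gene_ids, barcodes) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  gene_ids <- as.character(gene_ids)
  barcodes <- as.character(barcodes)
  if (nrow(counts) != length(gene_ids))
    stop("gene_ids length (", length(gene_ids), ") != row count (",
         nrow(counts), ")", call. = FALSE)
  if (ncol(counts) != length(barcodes))
    stop("barcodes length (", length(barcodes), ") != column count (",
         ncol(counts), ")", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicated gene_ids: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 3),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(barcodes))
    stop("duplicated barcodes: ",
         paste(utils::head(unique(barcodes[duplicated(barcodes)]), 3),
               collapse = ", "), call. = FALSE)
  if (length(counts@x) && (any(counts@x < 0) || any(counts@x != round(counts@x))))
    stop("counts must be non-negative integers", call. = FALSE)
  dimnames(counts) <- list(gene_ids, barcodes)
  structure(list(counts = counts, gene_ids = gene_ids, barcodes = barcodes),
            class = "ExpressionMatrix")
}

#' @rdname ExpressionMatrix
#' @param x an \code{ExpressionMatrix}.
#' @export
n_genes <- function(x) length(x$gene_ids)

#' @rdname ExpressionMatrix
#' @export
n_cells <- function(x) length(x$barcodes)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells, %d non-zero entries\n",
              n_genes(x), n_cells(x), length(x$counts@x)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Pool several expression matrices column-wise
#'
#' Restricts to the genes common to all inputs (order of the first) and
#' binds cells. Needed when scores must be comparable across samples, e.g.
#' a pooled-scoring group contrast. Barcodes must be unique across inputs;
#' set \code{prefix = TRUE} to disambiguate them with the list names.
#'
#' @param mats named list of [ExpressionMatrix] objects.
#' @param prefix prepend each matrix's list name to its barcodes.
#' @return A pooled [ExpressionMatrix].
#' @export
pool_matrices <- function(mats, prefix = FALSE) {
  stopifnot(length(mats) >= 1, all(vapply(mats, inherits, TRUE,
                                          "ExpressionMatrix")))
  genes <- Reduce(intersect, lapply(mats, `[[`, "gene_ids"))
  if (!length(genes)) stop("no genes common to all matrices", call. = FALSE)
  counts <- do.call(cbind, lapply(mats, function(m)
    m$counts[genes, , drop = FALSE]))
  barcodes <- unlist(lapply(seq_along(mats), function(i) {
    b <- mats[[i]]$barcodes
    if (prefix) paste0(names(mats)[i] %||% i, "_", b) else b
  }), use.names = FALSE)
  ExpressionMatrix(counts, genes, barcodes)
}

# Subset keeping class invariants.
subset_matrix <- function(m, genes = NULL, cells = NULL) {
  counts <- m$counts
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(cells)) counts <- counts[, cells, drop = FALSE]
  ExpressionMatrix(counts, rownames(counts), colnames(counts))
}
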