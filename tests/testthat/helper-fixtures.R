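# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

# A contig row with sensible defaults, overridable per field.
contig_row <- function(barcode = "AAACCTGAGAAACCAT-1", chain = "TRA",
                       v_gene = "TRAV1", d_gene = "", j_gene = "TRAJ1",
                       c_gene = "TRAC", cdr3 = "CAVRF", cdr3_nt = "TGTGCTGTTCGTTTT",
                       reads = 100L, umis = 5L, is_cell = TRUE,
                       high_confidence = TRUE, productive = TRUE,
                       raw_clonotype_id = "clonotype1") {
  data.table::data.table(
    barcode = barcode, is_cell = is_cell, high_confidence = high_confidence,
    chain = chain, v_gene = v_gene, d_gene = d_gene, j_gene = j_gene,
    c_gene = c_gene, cdr3 = cdr3, cdr3_nt = cdr3_nt, reads = reads,
    umis = umis, productive = productive,
    raw_clonotype_id = raw_clonotype_id, cdr3_aa = cdr3)
}

contig_table <- function(...) data.table::rbindlist(list(...), fill = TRUE)

# Paired TRA+TRB contigs for one barcode carrying a given clonotype id;
# clonotype identity is fully determined by `clone`.
paired_contigs <- function(barcode, clone = 1L, umis_a = 5L, umis_b = 7L) {
  nt <- function(i, chain) paste(rep(c("TGT", "GCT", "AAA")[i %% 3 + 1], 4 + i %% 3),
                                 collapse = "")
  rbind(
    contig_row(barcode, "TRA", v_gene = paste0("TRAV", clone),
               j_gene = paste0("TRAJ", clone), cdr3_nt = nt(clone, "A"),
               cdr3 = paste0("CA", clone, "F"), umis = umis_a),
    contig_row(barcode, "TRB", v_gene = paste0("TRBV", clone),
               d_gene = "TRBD1", j_gene = paste0("TRBJ", clone),
               c_gene = "TRBC1", cdr3_nt = nt(clone + 1, "B"),
               cdr3 = paste0("CB", clone, "F"), umis = umis_b))
}

# Small random ExpressionMatrix.
random_expression_matrix <- function(n_genes = 8, n_cells = 5,
                                     max_count = 6) {
  counts <- matrix(sample(0:max_count, n_genes * n_cells, replace = TRUE),
                   nrow = n_genes)
  ExpressionMatrix(counts, sprintf("g%03d", seq_len(n_genes)),
                   sprintf("BC%03d-%d", seq_len(n_cells), 1))
}

# Desk-scale synthetic cohort for recovery tests.
small_cohort_config <- function(seed = 11, n_cells = 300, n_genes = 200,
                                ...) {
  cohort_config(n_samples_per_arm = 1, n_cells_per_sample = n_cells,
                n_genes = n_genes, seed = seed, ...)
}

# Clonotype tables for every sample of a cohort, binned.
cohort_tables <- function(cohort, strategy = "nt+gene") {
  tabs <- lapply(names(cohort$samples), function(sid)
    bin_clonotypes(call_clonotypes(cohort$samples[[sid]]$contigs,
                                   strategy, sid)))
  stats::setNames(tabs, names(cohort$samples))
}

# Exact binomial central 99% interval on a proportion.
binom_ci99 <- function(p, n) {
  c(qbinom(0.005, n, p), qbinom(0.995, n, p)) / n
}
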