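test_that("identical chain pairs collapse to one clonotype", {
  contigs <- rbind(paired_contigs("AAA-1", clone = 1),
                   paired_contigs("CCC-1", clone = 1))
  t <- call_clonotypes(contigs)
  expect_equal(nrow(t$clones), 1)
  expect_equal(t$clones$clone_count, 2)
  expect_false(any(t$cells$single_chain))
})

test_that("per barcode and chain only the top-UMI contig contributes", {
  hi <- contig_row("AAA-1", "TRB", v_gene = "TRBV1", j_gene = "TRBJ1",
                   cdr3_nt = "TGTAAATTT", umis = 5L)
  lo <- contig_row("AAA-1", "TRB", v_gene = "TRBV9", j_gene = "TRBJ9",
                   cdr3_nt = "TGTCCCTTT", umis = 2L)
  t <- call_clonotypes(rbind(lo, hi))
  expect_match(t$cells$clonotype_key, "TRBV1")
  expect_no_match(t$cells$clonotype_key, "TRBV9")
  # UMI tie -> higher reads; reads tie -> lexicographically smaller cdr3_nt
  tie <- rbind(contig_row("B-1", "TRA", cdr3_nt = "TGTZZZ", reads = 10L),
               contig_row("B-1", "TRA", cdr3_nt = "TGTAAA", reads = 10L))
  expect_match(call_clonotypes(tie)$cells$clonotype_key, "TGTAAA")
  tie2 <- rbind(contig_row("B-1", "TRA", cdr3_nt = "TGTAAA", reads = 5L),
                contig_row("B-1", "TRA", cdr3_nt = "TGTZZZ", reads = 50L))
  expect_match(call_clonotypes(tie2)$cells$clonotype_key, "TGTZZZ")
})

test_that("non-cell, low-confidence, unproductive and odd chains are dropped", {
  contigs <- rbind(
    contig_row("A-1", is_cell = FALSE),
    contig_row("B-1", high_confidence = FALSE),
    contig_row("C-1", productive = FALSE),
    contig_row("D-1", chain = "Multi"),
    contig_row("E-1", chain = "None"))
  expect_equal(nrow(call_clonotypes(contigs)$cells), 0)
  expect_equal(nrow(call_clonotypes(contigs[0])$cells), 0)
})

test_that("calling agrees with a brute-force grouping oracle on 500 contigs", {
  withr::local_seed(77)
  n <- 500
  contigs <- contig_table(contig_row(
    barcode = paste0(sample(sprintf("BC%03d", 1:120), n, replace = TRUE), "-1"),
    chain = sample(c("TRA", "TRB"), n, replace = TRUE),
    v_gene = sample(paste0("V", 1:6), n, replace = TRUE),
    j_gene = sample(paste0("J", 1:4), n, replace = TRUE),
    cdr3_nt = sample(c("TGTAAA", "TGTCCC", "TGTGGG"), n, replace = TRUE),
    umis = sample(1:9, n, replace = TRUE),
    reads = sample(1:99, n, replace = TRUE)))

  oracle_keys <- local({
    df <- as.data.frame(contigs)
    keys <- character(0)
    for (bc in unique(df$barcode)) {
      sub <- df[df$barcode == bc, ]
      parts <- character(0)
      for (ch in unique(sub$chain)) {
        s <- sub[sub$chain == ch, ]
        s <- s[order(-s$umis, -s$reads, s$cdr3_nt), ][1, ]
        parts <- c(parts, paste(ch, s$v_gene, s$j_gene, s$cdr3_nt, sep = ":"))
      }
      keys[bc] <- paste(sort(parts), collapse = ";")
    }
    sort(as.vector(table(keys)))  # clone-size spectrum
  })
  t <- call_clonotypes(contigs)
  expect_equal(sort(t$clones$clone_count), unname(oracle_keys),
               ignore_attr = TRUE)
  expect_equal(sum(t$clones$clone_count), length(unique(contigs$barcode)))
})

test_that("aa strategy keys by cdr3_aa", {
  a <- contig_row("A-1", cdr3 = "CAXF", cdr3_nt = "TGTAAATTT")
  b <- contig_row("B-1", cdr3 = "CAXF", cdr3_nt = "TGTAAGTTT")  # synonymous
  t_nt <- call_clonotypes(rbind(a, b), "nt+gene")
  t_aa <- call_clonotypes(rbind(a, b), "aa")
  expect_equal(nrow(t_nt$clones), 2)
  expect_equal(nrow(t_aa$clones), 1)
})

test_that("bin boundaries follow the half-open (lo, hi] convention", {
  thr <- bin_thresholds()
  expect_identical(assign_bins(0.5), "hyperexpanded")
  expect_identical(assign_bins(0.005), "medium")
  expect_identical(assign_bins(5e-5), "rare")
  expect_identical(
    assign_bins(c(1e-4, 0.001, 0.01, 0.1, 1)),
    c("rare", "small", "medium", "large", "hyperexpanded"))
  expect_error(bin_thresholds(small_hi = 1e-5), "increasing")
})

test_that("binning matches an interval-membership oracle on random draws", {
  withr::local_seed(10)
  f <- c(10^runif(2000, -5, 0), 1e-4, 0.001, 0.01, 0.1, 1)
  oracle <- vapply(f, function(v) {
    if (v > 0.1) "hyperexpanded" else if (v > 0.01) "large"
    else if (v > 0.001) "medium" else if (v > 1e-4) "small" else "rare"
  }, character(1))
  expect_identical(assign_bins(f), oracle)
})

test_that("frequencies and bins satisfy conservation invariants", {
  withr::local_seed(55)
  contigs <- data.table::rbindlist(lapply(1:60, function(i)
    paired_contigs(sprintf("BC%03d-1", i), clone = sample(1:15, 1))))
  t <- bin_clonotypes(call_clonotypes(contigs))
  expect_equal(sum(t$clones$frequency), 1, tolerance = 1e-9)
  expect_equal(sum(t$clones$clone_count), nrow(t$cells))
  # frequency outside (0,1] rejected
  broken <- t
  broken$clones$clone_count[1] <- 0L
  expect_error(bin_clonotypes(broken), "invariant")
})

test_that("cells inherit their clonotype's bin; absent cells get none", {
  contigs <- data.table::rbindlist(lapply(1:3, function(i)
    paired_contigs(sprintf("T%d-1", i), clone = 1)))
  t <- bin_clonotypes(call_clonotypes(contigs))
  meta <- data.frame(barcode = c(sprintf("T%d-1", 1:3), "MAC-1"))
  labs <- cell_bin_labels(t, meta)
  expect_equal(labs$bin[match(sprintf("T%d-1", 1:3), labs$barcode)],
               rep("hyperexpanded", 3))
  expect_equal(labs$bin[labs$barcode == "MAC-1"], "none")
  expect_warning(cell_bin_labels(t, meta[1, , drop = FALSE]), "orphan")
})

test_that("ranking is frequency-descending with lexicographic tie-break", {
  contigs <- rbind(paired_contigs("A-1", 1), paired_contigs("B-1", 1),
                   paired_contigs("C-1", 2), paired_contigs("D-1", 3))
  t <- bin_clonotypes(call_clonotypes(contigs))
  r <- rank_clonotypes(t)
  expect_equal(r$rank, 1:3)
  expect_equal(r$clone_count, c(2L, 1L, 1L))
  tied <- r$clonotype_key[r$clone_count == 1]
  expect_identical(tied, sort(tied))
  expect_setequal(r$clonotype_key, t$clones$clonotype_key)
})

test_that("bin composition mirrors clone sizes 6/3/1", {
  contigs <- data.table::rbindlist(c(
    lapply(1:6, function(i) paired_contigs(sprintf("A%d-1", i), 1)),
    lapply(1:3, function(i) paired_contigs(sprintf("B%d-1", i), 2)),
    list(paired_contigs("C1-1", 3))))
  t <- bin_clonotypes(call_clonotypes(contigs, sample_id = "s1"))
  meta <- data.frame(sample_id = "s1", tissue = "tumor_d15", group = "normal")
  comp <- bin_composition(list(s1 = t), meta)
  # frequencies 0.6 and 0.3 both land in hyperexpanded, 0.1 in large,
  # so the per-bin cell shares are (6+3)/10 and 1/10
  cell <- comp$cell_level
  expect_equal(cell$pct[cell$bin == "hyperexpanded"], 90)
  expect_equal(cell$pct[cell$bin == "large"], 10)
  expect_equal(sum(cell$pct), 100, tolerance = 1e-9)
  clone <- comp$clonotype_level
  expect_equal(clone$pct[clone$bin == "hyperexpanded"], 200 / 3,
               tolerance = 1e-9)
  expect_equal(clone$pct[clone$bin == "large"], 100 / 3, tolerance = 1e-9)
})

test_that("bin composition equals a manifest recount on synthetic data", {
  cfg <- small_cohort_config(seed = 61, n_cells = 400, n_genes = 120)
  co <- generate_cohort(cfg)
  tables <- cohort_tables(co)
  comp <- bin_composition(tables, co$cell_meta)

  # Oracle: recount straight from the manifest's per-cell clonotype keys.
  man <- co$manifest$cells
  expected <- list()
  for (sid in unique(man$sample_id)) {
    sub <- man[man$sample_id == sid & !is.na(man$clonotype_key)]
    sizes <- table(sub$clonotype_key)
    f <- as.numeric(sizes) / sum(sizes)
    bins <- assign_bins(f)
    expected[[sid]] <- data.frame(tissue = sub$tissue[1], group = sub$group[1],
                                  bin = bins, cells = as.numeric(sizes))
  }
  exp_df <- do.call(rbind, expected)
  exp_counts <- aggregate(cells ~ tissue + group + bin, exp_df, sum)
  got <- as.data.frame(comp$cell_level)
  merged <- merge(got, exp_counts, by = c("tissue", "group", "bin"))
  expect_equal(nrow(merged), nrow(got))
  expect_equal(merged$count, merged$cells)
})

test_that("merging samples never changes within-sample bins", {
  c1 <- data.table::rbindlist(lapply(1:20, function(i)
    paired_contigs(sprintf("X%02d-1", i), clone = (i %% 4) + 1)))
  c2 <- data.table::rbindlist(lapply(1:5, function(i)
    paired_contigs(sprintf("Y%02d-1", i), clone = 9)))
  t1 <- bin_clonotypes(call_clonotypes(c1, sample_id = "s1"))
  t2 <- bin_clonotypes(call_clonotypes(c2, sample_id = "s2"))
  meta <- data.frame(sample_id = c("s1", "s2"),
                     tissue = "tumor_d15", group = c("normal", "sephin1"))
  comp <- bin_composition(list(s1 = t1, s2 = t2), meta)
  # s1 alone and s1-with-s2 give identical s1 bins (frequencies per sample)
  t1_alone <- bin_clonotypes(call_clonotypes(c1, sample_id = "s1"))
  expect_identical(t1$clones$bin, t1_alone$clones$bin)
  expect_equal(sum(comp$cell_level$pct[comp$cell_level$group == "normal"]),
               100, tolerance = 1e-9)
})
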