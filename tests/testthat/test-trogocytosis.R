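# Minimal two-sample world built by hand: sample s1 holds a Cd8 T cell, a
# Cd4 T cell, and macrophages that do or do not carry T-cell clonotypes.
hand_world <- function() {
  contigs_s1 <- data.table::rbindlist(list(
    paired_contigs("CD8A-1", clone = 1),
    paired_contigs("CD4A-1", clone = 2),
    paired_contigs("MAC1-1", clone = 1),   # shares with the Cd8 cell
    paired_contigs("MAC2-1", clone = 7)))  # private clonotype
  contigs_s2 <- paired_contigs("CD8A-1", clone = 5)  # same barcode, other sample
  meta <- data.table::data.table(
    barcode = c("CD8A-1", "CD4A-1", "MAC1-1", "MAC2-1", "MAC3-1", "CD8A-1"),
    sample_id = c(rep("s1", 5), "s2"),
    tissue = c(rep("tumor_d15", 5), "blood_d15"),
    group = "normal",
    cell_type = c("Cd8_T", "Cd4_T", "Macrophage", "Macrophage",
                  "Macrophage", "Macrophage"))
  tables <- list(
    s1 = bin_clonotypes(call_clonotypes(contigs_s1, sample_id = "s1")),
    s2 = bin_clonotypes(call_clonotypes(contigs_s2, sample_id = "s2")))
  list(meta = meta, tables = tables)
}

test_that("barcode matching is strictly per sample", {
  w <- hand_world()
  flags <- match_barcodes(w$meta, w$tables)
  # s1: all but MAC3 are in the contig table; s2: the macrophage IS in s2's
  # own table (clone 5), so it matches there, not through s1
  expect_identical(flags, c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  # drop s2's table: the s2 cell no longer matches even though an identical
  # barcode exists in s1's table
  flags2 <- match_barcodes(w$meta, w$tables["s1"])
  expect_identical(flags2[6], FALSE)
})

test_that("fractions count TCR+ macrophages within strata", {
  w <- hand_world()
  flags <- match_barcodes(w$meta, w$tables)
  frac <- tcr_mac_fraction(w$meta, flags)
  tumor <- frac[frac$tissue == "tumor_d15"]
  expect_equal(tumor$n_macrophages, 3L)
  expect_equal(tumor$n_tcr_pos, 2L)
  expect_equal(tumor$fraction, 2 / 3)
  # direct arithmetic example: 14 of 100
  meta <- data.table::data.table(
    barcode = sprintf("M%03d-1", 1:100), sample_id = "s",
    tissue = "tumor_d15", group = "normal", cell_type = "Macrophage")
  expect_equal(tcr_mac_fraction(meta, c(rep(TRUE, 14), rep(FALSE, 86)))$fraction,
               0.14)
  # no macrophages in a stratum -> NA fraction
  meta2 <- data.table::copy(meta)
  meta2$cell_type <- "B"
  expect_true(is.na(tcr_mac_fraction(meta2, rep(FALSE, 100))$fraction))
})

test_that("sharing assigns macrophages to the right compartment", {
  w <- hand_world()
  flags <- match_barcodes(w$meta, w$tables)
  shares <- shared_clonotype_fractions(w$meta, flags, w$tables)
  tumor <- shares[shares$tissue == "tumor_d15"]
  expect_equal(tumor$n_tcr_mac, 2L)       # MAC1 + MAC2
  expect_equal(tumor$n_cd8_share, 1L)     # MAC1 shares the Cd8 clonotype
  expect_equal(tumor$n_cd4_share, 0L)
  expect_equal(tumor$n_dual, 0L)
  expect_equal(tumor$cd8_share, 0.5)      # private MAC2 counts in neither
  pooled <- shares[shares$tissue == "all"]
  expect_equal(pooled$n_tcr_mac, 3L)      # + the s2 macrophage
})

test_that("TCR+ flags equal the manifest's assignments on synthetic data", {
  cfg <- small_cohort_config(seed = 71, n_cells = 500, n_genes = 120)
  co <- generate_cohort(cfg)
  tables <- cohort_tables(co)
  flags <- match_barcodes(co$cell_meta, tables)
  expect_identical(flags, !is.na(co$cell_meta$clonotype_key))
  # referential integrity: every TCR+ macrophage's clonotype is in its table
  meta <- co$cell_meta
  for (sid in names(tables)) {
    mac <- meta[meta$sample_id == sid & meta$true_type == "Macrophage" &
                  !is.na(meta$clonotype_key)]
    expect_true(all(mac$clonotype_key %in% tables[[sid]]$clones$clonotype_key))
  }
})

test_that("pipeline recovers planted transfer rates within +/-0.03 over 20 seeds", {
  props <- list(tumor_d15 = list(
    normal = c(Cd4_T = 0.12, Cd8_T = 0.22, Macrophage = 0.66),
    sephin1 = c(Cd4_T = 0.12, Cd8_T = 0.22, Macrophage = 0.66)))
  for (s in 1:20) {
    cfg <- cohort_config(
      n_samples_per_arm = 1, tissues = "tumor_d15",
      n_cells_per_sample = 1520, n_genes = 100,
      cell_type_proportions = props,
      trog_rate = c(blood_d0 = 0, blood_d15 = 0, tumor_d15 = 0.137),
      seed = 7000 + s)
    co <- generate_cohort(cfg)
    meta <- co$cell_meta
    meta$cell_type <- meta$true_type
    flags <- match_barcodes(meta, cohort_tables(co))
    frac <- tcr_mac_fraction(meta, flags)
    est <- sum(frac$n_tcr_pos) / sum(frac$n_macrophages)  # ~2000 macrophages
    expect_lte(abs(est - 0.137), 0.03)
  }
})

test_that("bin distribution among TCR+ macrophages sums to one per stratum", {
  w <- hand_world()
  flags <- match_barcodes(w$meta, w$tables)
  bins <- data.table::rbindlist(lapply(names(w$tables), function(sid)
    cbind(sample_id = sid,
          cell_bin_labels(w$tables[[sid]],
                          w$meta[w$meta$sample_id == sid]))))
  dist <- tcr_mac_bin_distribution(w$meta, flags, bins)
  sums <- tapply(dist$share, paste(dist$tissue, dist$group), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # 4 of 10 large, 6 of 10 small -> shares 0.4/0.6
  meta <- data.table::data.table(
    barcode = sprintf("M%02d-1", 1:10), sample_id = "s",
    tissue = "tumor_d15", group = "normal", cell_type = "Macrophage")
  b <- data.table::data.table(sample_id = "s", barcode = meta$barcode,
                              bin = rep(c("large", "small"), c(4, 6)))
  d <- tcr_mac_bin_distribution(meta, rep(TRUE, 10), b)
  expect_equal(d$share[d$bin == "large"], 0.4)
  expect_equal(d$share[d$bin == "small"], 0.6)
  # permutation invariance
  p <- sample(10)
  d2 <- tcr_mac_bin_distribution(meta[p], rep(TRUE, 10), b)
  expect_equal(as.data.frame(d2), as.data.frame(d))
})

test_that("damped expansion lowers the highly expanded share in macrophages", {
  cfg <- small_cohort_config(seed = 81, n_cells = 900, n_genes = 100,
                             tissues = "tumor_d15",
                             trog_rate = c(blood_d0 = 0, blood_d15 = 0,
                                           tumor_d15 = 0.3),
                             expansion_damp = 0.3)
  co <- generate_cohort(cfg)
  meta <- co$cell_meta
  meta$cell_type <- meta$true_type
  tables <- cohort_tables(co)
  flags <- match_barcodes(meta, tables)
  bins <- data.table::rbindlist(lapply(names(tables), function(sid)
    cbind(sample_id = sid,
          cell_bin_labels(tables[[sid]], meta[meta$sample_id == sid]))))
  d <- tcr_mac_bin_distribution(meta, flags, bins)
  high <- function(g) sum(d$share[d$group == g &
                                    d$bin %in% c("hyperexpanded", "large")])
  expect_lt(high("sephin1"), high("normal"))
})

test_that("setting macrophage contigs aside leaves T-cell bins unchanged", {
  cfg <- small_cohort_config(seed = 91, n_cells = 400, n_genes = 100,
                             tissues = "tumor_d15")
  co <- generate_cohort(cfg)
  sid <- names(co$samples)[1]
  meta <- co$cell_meta[co$cell_meta$sample_id == sid]
  mac_bc <- meta$barcode[meta$true_type == "Macrophage"]
  contigs <- co$samples[[sid]]$contigs
  no_mac <- contigs[!contigs$barcode %in% mac_bc]
  t_full <- bin_clonotypes(call_clonotypes(contigs, sample_id = sid))
  t_no <- bin_clonotypes(call_clonotypes(no_mac, sample_id = sid))
  # clonotype-level bins of clones held by T cells may shift only through
  # frequency renormalization; with the same denominator convention the
  # T-cell-only table is a subset of keys
  expect_true(all(t_no$clones$clonotype_key %in% t_full$clones$clonotype_key))
})
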