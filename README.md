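# clonomac

Paired single-cell expression + TCR repertoire analysis with TCR-bearing
macrophage detection, for studies that sequence matched 10X GEX and VDJ
libraries from a two-arm (treated vs control) mouse tumor design and ask
three questions:

1. **Is T-cell clonal expansion suppressed in the treated arm?**
   Clonotypes are called from contig tables (key:
   `chain:V:J:CDR3nt`, sorted over chains), their per-sample frequency
   `f = clone count / all clones of the sample` is computed, and each
   clonotype is binned: *hyperexpanded* `f ∈ (0.1, 1]`, *large*
   `(0.01, 0.1]`, *medium* `(0.001, 0.01]`, *small* `(1e-4, 0.001]` (an
   explicit *rare* label below that). Bin compositions are compared across
   arms with a chi-squared test on counts.
2. **Are macrophages pushed toward M2 polarization?** Per-cell
   expression-bin-matched module scores (24 bins, 100 control genes per
   signature gene) give `M1_to_M2 = S_M1 − S_M2`; group contrasts use the
   Wilcoxon rank-sum test per sample type, Holm-adjusted.
3. **Do macrophages carry T-cell receptors?** GEX/VDJ barcode
   intersection within each sample flags TCR+ macrophages; their fraction
   per stratum and the share of them whose clonotype also occurs among the
   same sample's Cd4+/Cd8+ T cells (Cd4-share / Cd8-share) quantify
   trogocytosis-like transfer.

A negative-binomial synthetic-cohort generator with planted, recoverable
ground truth (clone-size skew and its damping, signature shifts, per-tissue
TCR transfer rates, donor compartment mix) makes the whole chain testable
without access to any sequencing accession. Supporting tools include the
statistical toolkit (exact Wilcoxon, pooled t, chi-squared, Holm, stars),
a regulon specificity score `RSS = 1 − sqrt(JSD₂)`, and the caliper tumor
volume `V = d²·D/2`.

See `vignettes/clonomac-methods.Rmd` for the models, parameters and design
decisions.

## Worked example

```r
library(clonomac)

cfg <- run_config("synthetic",
  cohort = cohort_config(n_samples_per_arm = 1, n_cells_per_sample = 800,
                         n_genes = 800, seed = 7),
  out_dir = file.path(tempdir(), "demo"), use_true_types = TRUE,
  qc = list(min_genes_exclusive = 60),  # bound scaled to the 800-gene world
  seed = 7)
res <- run_pipeline(cfg)

as.data.frame(res$trog$fraction)
#>      tissue   group n_macrophages n_tcr_pos fraction
#> 1  blood_d0  normal           186         1  0.00538
#> 2  blood_d0 sephin1           191         1  0.00524
#> 3 blood_d15  normal           184         2  0.01087
#> 4 blood_d15 sephin1           191         0  0.00000
#> 5 tumor_d15  normal           373        52  0.13941
#> 6 tumor_d15 sephin1           355        35  0.09859
```

TCR+ macrophages concentrate in tumor (planted transfer rate 0.137 there
vs 0.005 in blood — the fractions recover them up to binomial noise at a
few hundred macrophages per stratum).

```r
as.data.frame(res$signatures$contrasts)[,
  c("signature", "tissue", "median_diff", "p_adj", "stars")]
#>             signature    tissue median_diff    p_adj stars
#> 1  cytotoxicity_Cd8_T  blood_d0     -0.0487 6.89e-01    ns
#> 2  cytotoxicity_Cd8_T blood_d15     -0.1785 3.11e-03    **
#> 3  cytotoxicity_Cd8_T tumor_d15     -0.2633 7.36e-08  ****
#> 4 M1_to_M2_Macrophage  blood_d0     -0.0445 4.34e-01    ns
#> 5 M1_to_M2_Macrophage blood_d15     -0.4018 1.15e-06  ****
#> 6 M1_to_M2_Macrophage tumor_d15     -0.3810 1.84e-12  ****
```

`median_diff` is treated minus control: cytotoxicity falls in Cd8 T cells
and macrophages shift toward M2 (negative M1_to_M2 difference) exactly in
the day-15 strata where the generator planted −0.5/+0.5 log-fold shifts;
day-0 blood, where nothing was planted, is null. p values are per-stratum
Wilcoxon, Holm-adjusted across the three strata.

```r
cl <- as.data.frame(res$bin_comp$cell_level)
cl[cl$tissue == "tumor_d15", ]
#>       tissue   group           bin count   pct
#> 9  tumor_d15  normal hyperexpanded   157  39.6
#> 10 tumor_d15  normal         large   138  34.8
#> 11 tumor_d15  normal        medium   101  25.5
#> 12 tumor_d15 sephin1        medium   377 100.0
```

With clone-size skew damped to 0.3 in the treated arm, its tumor repertoire
has no hyperexpanded or large clones left, while the control arm keeps 74%
of its TCR+ cells in those bins.

The same pipeline runs on real 10X outputs (`mode = "directory"`): per
sample a MatrixMarket matrix with features/barcodes sidecars plus a
`filtered_contig_annotations.csv`, and a `cell_metadata.tsv` (see
`write_cohort()` for the exact layout). Externally supplied cluster labels
are used when the metadata has a `cell_type` column.

A small CLI lives at `inst/cli/clonomac.R`
(`simulate | run | repertoire | score | stats` subcommands).

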