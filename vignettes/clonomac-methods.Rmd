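---
title: "clonomac: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clonomac: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`clonomac` links paired single-cell gene-expression (GEX) and TCR-enrichment
(VDJ) libraries at the cell-barcode level and quantifies three phenomena in
a two-arm mouse tumor study design: clonal expansion of T cells, macrophage
M1/M2 polarization, and TCR-bearing macrophages that share clonotypes with
T-cell compartments. This vignette explains the underlying models and every
tunable that matters, states what the synthetic cohort does and does not
emulate, and records the design decisions that were genuinely open.

## Clonotype calling and expansion bins

A clonotype is the sorted concatenation of a cell's retained chains,
`chain:v_gene:j_gene:cdr3_nt` (default) or the amino-acid variant
(`strategy = "aa"`). Retention requires `is_cell`, `high_confidence` and
`productive` all true and chain TRA or TRB; per barcode and chain the
highest-UMI contig wins (ties: more reads, then lexicographically smallest
CDR3 nucleotide sequence, so calling is deterministic). Cells with a single
chain are keyed by that chain and flagged rather than dropped — the data do
not say whether the original analysis kept them, and dropping them would
silently shrink every denominator.

A clonotype's frequency is its clone count divided by all clones of the
sample — the TCR-positive cells, not all cells; this is the literal reading
of the frequency definition the pipeline reimplements. Expansion bins are
half-open intervals (lo, hi]:

| bin | frequency |
|---|---|
| hyperexpanded | (0.1, 1] |
| large | (0.01, 0.1] |
| medium | (0.001, 0.01] |
| small | (1e-4, 0.001] |
| rare | (0, 1e-4] |

The half-open convention makes 1 attainable by a monoclonal sample and puts
the boundary 0.1 in "large". Frequencies at or below 1e-4 — below the
smallest published bin — get an explicit "rare" label so that per-sample
cell counts are conserved exactly; silent dropping would break the
invariant that bin counts sum to the number of TCR+ cells.

## Quality control and annotation

Genes must be expressed in at least 2 cells; cells must detect strictly
more than 100 and strictly fewer than 4000 genes (an inclusive reading is
available via `inclusive = TRUE`; the bounds themselves are arguments, and
desk-scale tests with tiny gene universes scale the lower bound down with
the universe). The gene filter runs before the cell filter, so "detected
genes" is counted on the gene-filtered matrix. The original study also
removed mitochondrial outliers *by eye* from a violin plot; a subjective
step cannot be reproduced in code, so it is exposed as an optional numeric
`mito_max` cutoff, default off — a documented divergence.

Cell typing replaces manual cluster annotation with a marker-score argmax:
each marker set is scored per cell as the mean of its markers' z-scored
(across cells) log1p-normalized expression (counts scaled to 10,000 per
cell, then log1p); the label is the argmax, ties broken by set order, and
cells whose scores are all non-positive are `unassigned`. Externally
supplied labels are accepted in directory mode, so a user with real cluster
annotations is never forced through the stand-in. The z-score scheme has a
known weakness: for a cell type that is rare in a sample, a single
stochastic count on one of its markers can produce a large z value, so a
few percent of cells leak into rare-type labels. On the default synthetic
cohort the argmax agrees with the planted types for about 97% of cells.

## Expression-bin-matched signature scoring

`module_score()` is the conventional single-cell "module score": genes are
ranked by mean expression (ties broken by gene symbol so the layout is
invariant to row order) and cut into `n_bins = 24` equal-size bins; each
signature gene is compared against `n_ctrl = 100` control genes drawn
uniformly with replacement from its own bin; a cell's score is the mean
expression of the signature genes minus the mean over the pooled control
draws. The defaults mirror the ecosystem convention for this scheme — the
procedure is named in the source material but no parameters are given.

Control draws are seeded by the *content* of the gene set (sorted symbols
combined with the user seed), never by row indices or argument position.
Three useful properties follow, and all are tested: scores are invariant to
gene row permutation; adding a constant to every log-expression value
leaves scores unchanged (the score is a difference of two means over the
same cell); and `m1_to_m2(A, B)` is exactly `-m1_to_m2(B, A)`, with the
self-difference identically zero.

The M1-to-M2 polarization score is the M2 module score subtracted from the
M1 module score; higher values mean M1 (pro-inflammatory) polarization. The
shipped M1/M2 and cytotoxicity lists are documented stand-ins assembled
from the standard mouse polarization and effector-marker literature — the
source material cites its lists without printing them — and every scoring
function accepts replacement sets (GMT or two-column TSV via
`read_gene_sets()`).

**Per-sample versus pooled scoring.** Scoring each sample separately is the
default, but bin-matched scores are *relative to the sample's own
expression layout*: a shift that affects every cell of a sample (the
degenerate case: a one-cell-type sample with a planted group-wide shift)
moves the signature genes into bins of equally elevated controls and
cancels. When scores feed a cross-arm contrast, they must share one bin
layout, so the group-contrast tests and the pipeline's
`pooled_scoring = TRUE` option score the sample-pooled matrix (barcodes
prefixed by sample to stay unique). In mixed-cell-type samples the default
per-sample scoring still detects cell-type-restricted shifts, because the
controls average over all cell types.

Group contrasts use the Wilcoxon rank-sum test per sample-type stratum,
Holm-adjusted across the three strata within one contrast (as the panel
legends of the emulated study describe), not across all contrasts globally.

## Statistical toolkit

* `chi_squared_composition()` — Pearson statistic on raw counts with
  margin-derived expectations; df = (r−1)(c−1); no continuity correction by
  default (Yates behind a flag, 2×2 only). Percentages are refused because
  the test is invalid on them; counts are always recoverable in-pipeline. A
  zero expected count errors; expected counts below 5 attach a warning.
* `wilcoxon_rank_sum()` — midranks for ties; exact two-sided p by full
  enumeration of all `choose(nx+ny, nx)` assignments when both arms have at
  most `exact_max_n = 8` observations and no ties (two-sided p is twice the
  smaller tail, capped at 1); otherwise the normal approximation with the
  tie-corrected variance and no continuity correction. Identical samples
  give p = 1 with a warning rather than an error.
* `t_test_unpaired()` — classic pooled-variance two-tailed Student's t
  (the named test), Welch by flag. Zero variance in both arms gives p = 1
  (equal means) or p = 0 (different means), with a warning.
* `holm_adjust()` — step-down: sort ascending, multiply the i-th smallest p
  by (m−i+1), running maximum, cap at 1, original order.
* `stars()` — strict thresholds: p < 1e-4 `****`, < 1e-3 `***`,
  < 0.01 `**`, < 0.05 `*`, else `ns`; p = 0.05 is `ns`.
* `regulon_specificity_score()` — RSS = 1 − sqrt(JSD) between the regulon's
  cell-normalized activity distribution and each label's indicator
  distribution; base-2 logs so JSD (hence RSS) is bounded in [0, 1], the
  convention of the RSS literature. Network inference and regulon-activity
  computation are out of scope — the function post-processes a supplied
  activity matrix.
* `tumor_volume()` — V = d²·D/2 from caliper diameters in mm; d > D errors
  (swapped diameters), as does any non-positive diameter.

## The synthetic cohort: what it states and what it omits

`cohort_config()` defaults *are* the emulated world: two arms
(normal/sephin1), three sample types (blood day 0, blood day 15, tumor
day 15), two replicate samples per arm per tissue — the study's 12-sample
design — at desk scale (1000 cells/sample, 2000 genes). Counts are
negative-binomial (dispersion `size = 2`, typical of UMI data) with
per-gene baseline means log-normal (sdlog 1.2) around `nb_mean = 0.3` so
that all 24 expression bins are populated; curated marker and signature
genes are pinned at a mean of 1 UMI, reflecting that canonical markers sit
well above the transcriptome-wide median — with long-tail baselines a large
fraction of markers would be undetectable, which no one would call a usable
marker panel. Markers are elevated 5-fold in their owning type.
Mitochondrial genes (13, `mt-*`) are elevated 15-fold so the mitochondrial
fraction is realistic.

Planted effects, all recoverable from the manifest: a +0.5 log-fold M2
shift in treated-arm day-15 macrophages and a −0.5 cytotoxicity shift in
treated-arm day-15 Cd8/NK/NKT cells; clone sizes drawn per compartment
(Cd4, Cd8, NKT) from a power law with exponent 2 — the source gives no
quantitative clone-size law, so the exponent is a flagged modelling choice
— damped in the treated arm by `expansion_damp = 0.3` (the exponent is
divided by the damping factor, so damping strictly reduces the expected
top-clone share; a log-normal alternative scales sdlog); and TCR transfer
to macrophages at per-tissue rates 0.137 (tumor) and 0.005 (blood) — the
two percentages the emulated study prints — with donors drawn 0.8 Cd8 /
0.2 Cd4, uniformly within the compartment (equivalently,
clone-size-proportional at the clonotype level). Transfer copies the
donor's contig rows verbatim under the macrophage's barcode, modelling
mRNA-level TCR presence and making compartment-share ground truth exact.

Reproducibility: one RNG stream per sample is derived from
`(seed, sample_id)` through a stated polynomial string hash, so outputs do
not depend on generation order; clone-size draws take their own derived
seeds. Two calls with one config are identical.

Not emulated — and therefore not established by any green test here:
transcriptome-wide co-expression structure, doublets, ambient RNA,
batch/chemistry effects, realistic V/J usage or CDR3 length spectra, and
biological heterogeneity within a cell type. A green recovery test
demonstrates that the pipeline measures what the generator planted, at the
stated noise level; it cannot certify performance on real droplet data.

## Numerical and degenerate-input choices

* Frequencies outside (0, 1] are invariant errors, not warnings.
* `qc_filter` warns (does not error) when every cell is removed, and
  reports a per-stage in/out ledger in the pipeline run manifest, since the
  emulated study publishes only its post-QC total.
* Zero-variance genes z-score to 0 in annotation; all-zero cells stay
  all-zero under normalization and come out `unassigned`.
* All-zero regulon activity yields NA RSS with a warning, never silent 0.
* Strata without macrophages report NA fractions, explicitly "missing";
  empty strata in composition tables are absent rather than zero-filled.
* Clonotype-sharing is computed per sample and then aggregated; both
  per-stratum and pooled (`tissue = "all"`) rows are emitted because the
  emulated figure's pooling is ambiguous.
* The acceptance report recovers the planted transfer rates on a scaled-up
  macrophage-rich cohort using ground-truth types, isolating trogocytosis
  detection from annotation leakage (a few percent of TCR+ T cells
  mislabelled as macrophages would otherwise inflate the small blood
  percentage); annotation accuracy is tested separately.

## Known limitations

The marker-score annotator is a stand-in for manual curation and inherits
rare-type z-score inflation; single-chain cells are keyed by one chain,
which can merge distinct clonotypes that differ only in the missing chain;
the Wilcoxon normal approximation omits the continuity correction (the
exact branch, which the acceptance surface exercises, is unaffected); and
the shipped M1/M2 lists are literature stand-ins, not the unpublished
originals.
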