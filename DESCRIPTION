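Package: clonomac
Title: Paired Single-Cell Expression and TCR Repertoire Analysis with
    TCR-Bearing Macrophage Detection
Version: 0.1.0
Authors@R:
    person("Repertoire", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline linking paired 10X-style gene-expression
    and TCR-enrichment libraries at the cell-barcode level: quality-control
    filtering, marker-score cell-type annotation, clonotype calling and
    frequency-based expansion binning (hyperexpanded/large/medium/small),
    expression-bin-matched gene-signature scoring including the M1-to-M2
    macrophage polarization score, detection of TCR-bearing macrophages and
    their clonotype sharing with Cd4+/Cd8+ T-cell compartments, a regulon
    specificity score, and the associated group-comparison statistics
    (chi-squared composition tests, exact Wilcoxon rank-sum, unpaired t test,
    Bonferroni-Holm adjustment). Ships a negative-binomial synthetic-cohort
    generator with planted, recoverable ground truth so every stage is
    testable without access to the original sequencing accession.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
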