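Package: crisprascreen
Title: Multiplex Single-Cell CRISPRa Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for multiplex single-cell CRISPR activation
    (CRISPRa) screens of cis-regulatory elements. Cells receive random
    combinations of gRNAs at high multiplicity of integration; the package
    assigns gRNAs to cells from capture UMI counts, partitions cells into
    carrier and control groups for every gRNA, tests all genes within a
    1 Mb cis-window by Wilcoxon rank-sum, converts raw P-values to empirical
    P-values against non-targeting-control tests, and calls hits at an
    empirical FDR threshold. Also included: screen-level summaries (sign
    proportion, proximity enrichment, cross-context correlation), the exact
    3-vs-21 singleton bulk-validation test, a five-round threshold-relaxation
    gRNA selection procedure with CAGE-based TSS-distance annotation, and a
    synthetic-screen generator with known ground truth for power and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
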