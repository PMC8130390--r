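Package: hepsig
Title: Hepatocyte Gene Signatures and Index-Based Cell Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives cell-type-specific gene signatures from single-cell
    atlases using fraction-of-cells-expressing profiles, a two-threshold
    specificity filter, Ward (ward.D2) hierarchical clustering and a
    bulk-tissue refinement step; scores bulk samples and single cells with
    signature indexes (median or mean of per-gene Z-scores); fits a
    two-component exponential plus normal mixture to index distributions to
    derive a hepatocyte-calling threshold; classifies proliferative
    hepatocytes and SLC40A1-stratified macrophage groups in tumor and
    para-carcinoma tissue; and provides Wilcoxon rank-sum differential
    expression with Bonferroni control plus index correlation and t-test
    group comparisons. Ships seeded synthetic-data generators that emulate
    the statistical structure of the supported inputs with ground-truth
    labels, so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
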