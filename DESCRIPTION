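Package: icbmm
Title: Multimodal Integration of Cytotoxic T Cell and Tumor Genomic
    Features for Immunotherapy Response Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling response to immune checkpoint blockade (ICB) in
    non-small cell lung cancer from paired tumor-extrinsic and tumor-intrinsic
    features. Implements single-cell RNA/protein quality control, normalization,
    T-cell compartment gating and Wilcoxon rank-sum differential expression;
    gene-signature derivation and cytotoxic-score computation; TCR clonotype
    calling, clonal-expansion statistics, Shannon-entropy diversity with
    Hutcheson's t-test, and directed clone-sharing graphs; tumor mutational
    burden with assay-specific variant filters, HLA class I loss-of-heterozygosity
    calling from allele-specific coverage, and PD-L1 categorization; Kaplan-Meier
    estimation, log-rank testing and ridge-penalized Cox proportional hazards
    with Breslow tie handling; and a multimodal out-of-fold Cox ensemble risk
    score with median binarization. A synthetic-data module generates all inputs
    with the statistical structure the analysis assumes, so the full pipeline is
    testable without access to restricted patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
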