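Package: mirProt
Title: Integrated miRNA and Label-Free Proteomics Differential Expression
    with Inverse-Expression Target Pairing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Re-usable pipeline for integrating miRNA microarray and
    label-free (LFQ) proteomics screens of a two-group cell-line design:
    MaxQuant-style protein-groups cleaning, valid-value filtering,
    left-censored (MNAR) downshifted-Gaussian imputation, Welch-test /
    z-score / fold-change combined tiering, two-sample power design checks
    via the noncentral t distribution, signed-fold miRNA differential
    expression with cytoband and common-fragile-site annotation,
    2^-ddCT relative qPCR quantification, inverse-expression
    miRNA-to-protein target pairing over user-supplied target maps, and
    ungapped mismatch scanning of EVI1 binding motifs over promoter
    windows. Ships a synthetic-data module that emulates the statistical
    structure of such screens (log-normal intensities, intensity-dependent
    missingness, planted effects, inverse miRNA/target pairs) so the whole
    pipeline is exercisable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Proteomics, Transcriptomics, DifferentialExpression, Software
RoxygenNote: 7.3.3
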