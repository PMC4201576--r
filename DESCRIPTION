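Package: refstab
Title: Reference-Protein Stability Assessment for Quantitative Western Blot
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for validating endogenous loading controls (reference
    proteins) for quantitative western blot in designed animal studies.
    Implements fold-difference screening with Welch t-tests across
    treated-versus-control conditions, a model-based variance-decomposition
    stability value (NormFinder) for single candidates and all geometric-mean
    combinations across training/validation cohorts, a pairwise comparative
    normalization statistic adapted from the comparative delta-Cq method,
    linear-model attribution of each candidate's contribution to combination
    stability, and protein-mRNA concordance via Spearman correlation with
    AS 89 significance. Includes a synthetic-data generator that reproduces
    a 192-animal, 47-condition dioxin (TCDD) dose-response and timecourse
    design so that every stage of the analysis is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
biocViews: Proteomics, Normalization, QualityControl, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
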