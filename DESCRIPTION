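Package: metabodereg
Title: Quantitative Efficacy Evaluation from Time-Course Untargeted
    Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for quantifying treatment efficacy from time-course
    untargeted metabolomics peak tables.  Implements the standard
    preprocessing chain for LC/MS and GC/MS intensity matrices
    (blank-ratio background filtering, the 80% rule, pooled-QC relative
    standard deviation filtering, total-ion-intensity normalization, ion
    fusion and Pareto scaling), removal of exogenous decoction-derived
    features, OPLS-DA based biomarker screening with VIP and
    Benjamini-Hochberg adjusted Mann-Whitney tests, phenotype-anchored
    Spearman filtering, PCA group trajectories, a principal-curve
    Metabolites Deregulation Score (MDS) with time-resolved areas under
    the curve, and the RAUC statistic (area of the absolute fold-change
    curve relative to same-day controls).  A synthetic-data generator
    emulating a six-group rodent toxicity study with ground truth makes
    every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
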