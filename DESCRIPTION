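Package: subtypeConcord
Title: Intrinsic Breast-Cancer Subtyping Methods and Their Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nearest-centroid (PAM50-style Spearman and Prosigna-style
    Pearson) and binary-rule naive-Bayes (AIMS-style) intrinsic breast-cancer
    subtype classifiers, together with the expression pre-processing they
    require (log2 counts per million, quantile normalization, upper-quartile
    FPKM, housekeeping normalization, subgroup-specific percentile and median
    gene centering, per-gene affine technical calibration), cross-method
    concordance statistics (contingency tables, overall agreement, Cohen's
    kappa with label merging, conditional misassignment rates, subtype
    distributions, clear-defined versus discord partition), a borderline
    subtype analysis built on top-two centroid-correlation margins with a
    second-centroid switching experiment, and a seeded synthetic-data
    generator producing ground-truthed cohorts with composition bias and
    platform distortions so that every pipeline stage is testable without
    access to trial expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
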