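Package: mega
Title: Monotonically Expressed Gene Analysis Across Tumor Stage Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores genes by the monotonicity of their expression across
    ordinal lymph-node (N) and tumor-size (T) pathological stages, selects
    monotonically expressed gene (MEG) signatures, validates them by
    directional p-value meta-analysis (Fisher, Stouffer, cumulative
    binomial) with background-bias correction against random gene sets,
    and derives a signed z-sum prognostic risk score with ROC/AUC and
    tertile risk groups.  Includes comparator rankings (per-gene two-way
    ANOVA and multiple regression on stage factors) and a seeded
    synthetic-cohort generator so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
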