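Package: compss
Title: Composite Metrics for Selecting Computer-Generated Protein Sequences
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores, calibrates and filters computer-generated enzyme
    sequences for the likelihood of in vitro activity. Implements
    alignment-free sequence metrics (tandem-repeat scores, net charge),
    alignment-based metrics against a natural training set (identity to the
    closest training sequence, substitution-matrix mutant-position means,
    top-k homology), masked language-model likelihood schedules with a
    pluggable scorer contract, structure-derived metrics (Shrake-Rupley
    solvent-accessible surface area with polar/apolar decomposition,
    per-residue prediction confidence, inverse-folding scorer adapters),
    the evaluation statistics used to calibrate them (AUC-ROC, Spearman,
    Fisher exact, percentile thresholds, quadrant deconvolution), a
    multi-stage selection filter with identity-matched negative controls,
    spectrophotometric assay analysis, and seeded synthetic fixtures so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    bio3d,
    jsonlite,
    rlang,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
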