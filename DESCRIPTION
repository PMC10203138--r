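Package: cytometa
Title: Cross-Patient Phenotypic Meta-Clustering of Mass-Cytometry Subclones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for single-cell mass-cytometry (CyTOF) subclone
    phenotyping in plasma-cell malignancies: arcsinh preprocessing and
    monotypic plasma-cell gating, per-patient unsupervised clustering,
    two-part (hurdle) differential-expression Z-score signatures,
    cross-patient meta-clustering of cluster signatures with
    defining-marker calls, association of meta-cluster abundance and
    presence with clinical covariates and overall survival, and a
    rank-summation gene-signature activity score for validation on bulk
    expression cohorts. Includes a synthetic cohort generator with
    planted phenotypic archetypes, clinical effects and survival models
    so every stage can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
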