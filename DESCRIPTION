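Package: lutdsig
Title: Marker-Panel Discovery and Imbalanced-Cohort Classification for
    Lower Urinary Tract Dysfunction Transcriptomics
Version: 0.1.0
Authors@R:
    person("LUTD", "Signatures Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering small mRNA signatures that separate
    lower-urinary-tract-dysfunction phenotypes (bladder pain syndrome,
    detrusor overactivity, controls) from compact QPCR gene panels.
    Covers delta-delta-Ct log2 fold-change computation, exclusivity-based
    marker-panel selection from differential-expression tables, an
    exploratory statistics battery (z-score deviation calls, ECDF,
    correlograms, normality and group-difference tests), unsupervised
    learning (PCA with variable contributions, hierarchical / k-means /
    PAM clustering, elbow and cluster-transition diagnostics, Mahalanobis
    distances), and a supervised pipeline for small imbalanced cohorts:
    one-vs-one task construction, stratified repeated and nested
    cross-validation, recursive feature elimination with cross-validation,
    SMOTE-family oversampling fitted inside training folds only, a
    twelve-classifier grid, seven evaluation metrics, and a radar-area
    cumulative performance score. A seeded synthetic-data generator with
    planted ground truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
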