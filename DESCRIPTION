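Package: connpls
Title: Behavioural Partial Least Squares for Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Connectome", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links whole-brain resting-state functional connectivity to
    multi-domain behavioural measures with behavioural partial least squares
    (PLS): singular value decomposition of the cross-covariance matrix,
    permutation and bootstrap inference, leakage-safe repeated k-fold
    cross-validation with in-fold confound residualization, network-level
    summaries of the significant edge pattern, spatial-autocorrelation-
    preserving surrogate tests against per-region annotation maps, and
    connectome-based prediction (support vector regression) and two-group
    classification (RBF-kernel support vector machine) with nested
    cross-validation and label-permutation significance. Ships a synthetic
    cohort generator with a planted latent dimension so every stage is
    testable without restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
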