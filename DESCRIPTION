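Package: qsardrift
Title: Version Drift Analysis for ICH M7 (Q)SAR Mutagenicity Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how (Q)SAR bacterial-mutagenicity
    predictions for pharmaceutical-impurity-like compounds change across
    software versions. Provides chemical-space-matched dataset curation
    (structure standardization, mixture and metal filtering, fragment
    fingerprints, Tanimoto similarity selection, similarity graphs and
    structural-alert profiling), harmonization of vendor-specific
    prediction vocabularies to a common four-category scale, ICH M7
    two-model consensus calls, transition-matrix analysis of
    version-to-version prediction changes, and a synthetic generator of
    multi-vendor, multi-version prediction histories for testing the
    pipeline without proprietary model software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    igraph,
    Matrix,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
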