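Package: protnet
Title: Weighted Correlation Network Analysis of Serum Proteomic Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects clusters (modules) of correlated analytes in serum
    immunoassay panels with an unsigned weighted correlation network
    (soft-thresholded adjacency, topological overlap, average-linkage
    clustering with adaptive branch pruning), summarizes each module by
    its eigenprotein and module membership (kME), and relates modules to
    depression diagnosis and individual depressive symptoms through
    tiered covariate-adjusted linear contrasts with Bonferroni control.
    Includes split-half resampling to assess module stability and a
    synthetic cohort generator with planted factor structure, detection
    limit censoring and ordinal symptom items, so the full pipeline can
    be exercised and validated without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
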