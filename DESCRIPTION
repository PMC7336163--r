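Package: ddfnc
Title: Decentralized Dynamic Functional Network Connectivity
Version: 0.1.0
Authors@R:
    person("ddfnc", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Simulates a multi-site neuroimaging consortium and runs the full
    dynamic functional network connectivity (dFNC) pipeline without pooling
    raw data: decentralized two-stage PCA (serial round-robin and recursive
    parallel subspace merging), decentralized group spatial ICA with infomax
    at an aggregator site, GICA1 back-reconstruction of subject timecourses,
    sliding-window correlation, exemplar selection, and decentralized K-means
    clustering of windowed connectivity into recurring states (multishot
    Lloyd's, multishot gradient descent, and single-shot centroid merging).
    Includes generators for planted-state synthetic fMRI-like data, pooled
    reference implementations for equivalence checking, Hungarian component
    matching, the Moreau-Amari index, and group contrasts on state medians.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
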