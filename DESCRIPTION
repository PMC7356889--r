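Package: fffmon
Title: Multivariate Monitoring of Formulation, Fill and Finish Batch Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for multivariate statistical process monitoring of
    formulation, fill and finish (FFF) batch processes. Aligns heterogeneous
    lot data (quality-database records, lyophilization time series, a
    continuous sterile-filtration sensor stream) into per-lot batch objects,
    cleans sensor artifacts (terminal pressure peaks, operator-induced
    spikes), segments step-shaped signals into plateau and slope phases with
    an adaptive threshold algorithm, sets multi-signal rule-based phases,
    extracts per-phase features into a lot-by-feature matrix, and detects
    abnormal lots with robust principal component analysis (ROBPCA)
    score/orthogonal-distance diagnostics, quadrant classification and
    per-variable contribution decomposition. Includes a classical-PCA
    comparison (Hotelling T2, normalized DModX) and a synthetic campaign
    generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
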