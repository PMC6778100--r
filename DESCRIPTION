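Package: connectostat
Title: Graph-Theoretic Group Analysis of Resting-State Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds functional connectomes from regional resting-state fMRI
    time series and tests for group differences in their topology. Covers the
    full analysis chain: Pearson correlation matrices with optional Fisher
    z-transform, covariate residualization, healthy-reference positive-edge
    masking, short-distance edge exclusion, proportional density thresholding,
    binary graph metrics (mean clustering coefficient, global efficiency,
    degree assortativity), rich-club curves normalized against
    degree-preserving Maslov-Sneppen null networks with permutation regime
    detection, permutation two-sample t-tests across a density sweep with
    Benjamini-Hochberg FDR control, and the network-based statistic (NBS)
    with max-component permutation family-wise error control. A synthetic
    cohort generator produces multi-group regional time series from
    block-structured population covariances with planted edge effects, so the
    whole pipeline is testable without access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
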