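Package: pslearn
Title: Cross-Language Neural Pattern Similarity and Novel Word Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline linking pre-training cross-language
    neural pattern similarity to the rate of novel word learning. Provides
    event-schedule generators for slow event-related and jittered fMRI designs,
    a forward BOLD model with controllable cross-language representational
    similarity, single-item (beta-series) GLM estimation with a double-gamma
    HRF and discrete-cosine high-pass filtering, ROI-based representational
    similarity analysis in two variants (mean pairwise and averaged-pattern
    Fisher-z similarity), power-law learning-curve fitting with a
    goodness-of-fit inclusion rule, and group-level statistics
    (repeated-measures ANOVA, ROI-wise brain-behavior Pearson correlation).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
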