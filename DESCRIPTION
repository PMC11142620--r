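Package: featnet
Title: Feature-Type Composition and Semantic Network Structure of Early Vocabularies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how semantic feature types (encyclopedic,
    functional, perceptual, taxonomic) shape early noun and verb learning.
    Implements feature-norm composition analysis for CDI-style lexicons
    (per-word feature-type proportions, Welch and two-way ANOVA comparisons
    with estimated marginal mean contrasts), construction of per-child
    feature-type-restricted weighted semantic networks, normalization of
    mean weighted degree against random networks of matched noun-verb
    composition (PCA-guided sampling of the vocabulary-size space,
    interpolated and kernel-smoothed degree histograms, percentile ranks),
    and cluster-based permutation tests across vocabulary-size bins.
    Includes a synthetic-data generator for feature norms and CDI-like
    vocabulary trajectories so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    emmeans,
    interp,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
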