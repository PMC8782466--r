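Package: actimood
Title: Actigraphy Variability, Complexity and Similarity-Graph Features for
    Mood-State Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw wrist-accelerometer recordings into per-minute activity
    counts and computes linear variability (coefficient of variation, RMSSD,
    lag-1 autocorrelation), nonlinear complexity (sample entropy, symbolic
    dynamics) and similarity-graph features (edges, bridges, components,
    missing direct edges, isolated time points, 3-cliques) of activity
    epochs. Provides paired within-subject statistics between mood states
    (paired t, exact Wilcoxon signed-rank, Bonferroni thresholds, Pearson
    correlation matrices), a phenomenological synthetic cohort generator for
    paired manic/euthymic recordings, and a configuration-driven pipeline
    tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
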