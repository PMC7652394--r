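Package: mnlineage
Title: Bayesian Lineage-Tree Analysis of Micronucleus Formation and
    Cell-Cycle Fate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing live-cell imaging lineage trees of cells
    carrying a single defined sister chromatid fusion (SCF). Reads tidy
    per-cell-cycle tables, builds lineage trees, and fits hierarchical
    Bayesian models of micronucleus (MN) formation (Bernoulli with a
    logit link) and interphase duration (log-normal, exponential or
    gamma) with optional per-lineage random intercepts. Models are
    compared by the widely applicable information criterion (WAIC) on
    the generalization-loss scale; posterior-predictive MN probabilities,
    fold changes, duration distributions and interquartile ranges are
    derived from the fits. Includes a branching-process simulator that
    emulates the statistical structure of such live-cell datasets
    (movie-length censoring, frame quantization, marker fading, sporadic
    death and fusion events), matched sister-pair comparisons with a
    chi-square test, and deterministic SVG lineage-tree rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
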