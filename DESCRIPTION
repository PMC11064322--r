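Package: cladoda
Title: Phylogeny-Aware Hierarchical Differential Abundance Testing on
    Cladograms of Means
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential abundance analysis for microbiome taxa tables that
    exploits the taxonomic tree instead of treating taxa as exchangeable
    hypotheses. Abundances are log- or relative-normalized and merged at a
    chosen taxonomy level (including grouped principal-component merging),
    arranged on a cladogram of means in which every internal node carries the
    per-sample average of its direct descendants, and tested hierarchically:
    an a priori nested ANOVA gate decides whether a sample label is
    microbially explainable at all, a trajectory Mann-Whitney (or Spearman)
    descent with a sister false-discovery correction localizes the signal,
    and a Bonferroni-corrected leaf test rescues rare taxa without a
    significant ancestor chain. Includes a ground-truth-free evaluation score
    comparing discoveries under real and shuffled labels (RSP), truth-based
    confusion metrics, hierarchical Gaussian and spike-in microbiome
    simulators, and plot-data builders for cladogram and taxon-interaction
    displays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    optparse
Config/testthat/edition: 3
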