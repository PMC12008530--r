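Package: diglyq
Title: Quantitative Analysis of diGly (K-epsilon-GG) Ubiquitinome Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative synaptic ubiquitinome analysis from
    diGly (K-epsilon-GG) remnant profiling. Implements the discovery-stage
    TMT reporter-ion workflow (site filtering, left-censored imputation at
    the channel minimum, Tukey median-polish normalization, empirical-Bayes
    moderated linear-model testing with Storey q-values and dual
    fold-change/q significance calls), the targeted PRM workflow
    (transition quality control, light-to-heavy ratio-of-sums
    summarization, injection-replicate averaging, batch-aware differential
    testing), a peptidoform-crosstalk conservation model that separates
    phospho-conversion from net (de)ubiquitination and predicts the
    phosphatase-control outcome, cross-method comparisons (TMT-vs-PRM
    ratio-compression regression, flanking sequence-window site matching,
    sites-per-protein inventories), and a synthetic-data generator that
    emulates the statistical structure of such experiments for testing and
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
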