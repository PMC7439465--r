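Package: spcompare
Title: Label-Free Spectral-Count Differential Analysis with DAve/DCI Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for label-free differential proteomics based on
    spectral counting. Reads per-run protein identification lists (tab-separated
    search-engine exports), aligns them into a protein-by-run count matrix,
    averages spectral counts per experimental condition, and scores pairwise
    differential abundance with the bounded differential-average index
    DAve = 2(X - Y)/(X + Y) and the abundance-weighted differential confidence
    index DCI = (X + Y)(X - Y)/2, with inclusive significance thresholds.
    Includes set-partition (Venn) analysis of per-strain detection, a
    color-coded differential table, network-table export for graph tools, a
    synthetic spectral-count generator with known ground truth (Poisson or
    negative-binomial noise with detection dropout), and recovery metrics
    (sensitivity, false-discovery proportion, false-positive rate) for
    calibration of the threshold filter.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
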