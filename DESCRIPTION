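Package: htsort
Title: Spike Sorting for High-Density Multi-Electrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spike-sorting pipeline for dense extracellular multi-electrode
    array recordings. Detects spikes per channel with a robust median-based
    amplitude threshold and sliding-window peak alignment, removes cross-channel
    duplicates of each spike event by divide-and-conquer best-channel selection,
    clusters per-electrode snippet groups with principal-component features and
    hierarchical density-based clustering (HDBSCAN) with explicit outlier
    marking, merges redundant templates across neighboring electrodes, and
    resolves temporally overlapping spikes by greedy template-matching pursuit.
    Includes a ground-truth synthetic recording generator and an evaluation
    suite reporting per-unit accuracy, precision, and recall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
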