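Package: nilscape
Title: Fine-Scale Crossover Landscape Analysis for Nested Near-Isogenic Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and testing fine-scale meiotic crossover
    rate variation from marker-genotyped panels of nested near-isogenic
    lines (NILs). Calls crossover breakpoints from SNP genotype matrices,
    tabulates per-interval crossover counts at full and ~25 kb resolutions,
    quantifies rate heterogeneity with Lorenz curves and Gini coefficients,
    tests rate uniformity against design-aware multinomial simulation nulls,
    fits exact maximum-likelihood piecewise-constant rate segmentations by
    dynamic programming, simulates gamma-distributed per-kilobase rate
    landscapes to assess hotspot compatibility, and scans genomic correlates
    and exhaustive double-strand DNA k-mer motifs with Poisson log-linear
    models under GC-preserving sequence-permutation control. Includes a
    synthetic-data generator emulating a two-cross NIL sampling design so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
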