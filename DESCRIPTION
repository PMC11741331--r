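Package: ibdsegs
Title: Fast Exact Simulation of Identity-by-Descent Segments at a Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the lengths of identity-by-descent (IBD) haplotype
    segments overlapping a focal genomic location for large samples under a
    hybrid discrete Wright-Fisher / Kingman coalescent with piecewise
    exponential demography and optional hard selective sweeps. Per-branch
    exponential recombination endpoints yield exact Gamma-distributed pairwise
    segment lengths; pruning of undetectable lineages and merging of lineages
    with shared endpoints make runtime approximately linear in sample size
    while remaining exact for all segments longer than a Morgans detection
    threshold. Closed-form coalescent and endpoint-sharing formulas are
    exposed both as a public API and as built-in correctness oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
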