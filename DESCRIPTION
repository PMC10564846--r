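Package: aerovirome
Title: Cross-Ecosystem Dispersal Analysis of Marine Viruses Along the Water Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the dispersal of marine viruses from the
    sea surface (sea foams, surface microlayer, subsurface water) into
    boundary-layer aerosols and precipitation. Implements breadth-based
    presence calling of viral scaffolds and metagenome-assembled genomes
    from identity-filtered read coverage, cross-ecosystem occupancy and
    enrichment-ratio statistics, Markov-background-corrected d2*
    oligonucleotide dissimilarity for virus-host prediction, CRISPR
    direct-repeat-guided spacer extraction and protospacer matching,
    frequency-based variant overlap analysis, backward air-mass trajectory
    scoring (time over sea, marine loading conditions), frozen-fraction
    Poisson estimation of ice-nucleating-particle spectra, and station-level
    neuston statistics (enrichment factors, virus-host ratios, correlations,
    interaction linear models). A seed-deterministic synthetic-data
    generator produces ground-truth-bearing inputs with the statistical
    structure the analysis assumes, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    methods,
    stats,
    utils,
    vegan,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr
Config/testthat/edition: 3
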