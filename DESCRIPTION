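Package: rholandscape
Title: Post-Processing and Validation of LD-Based Recombination Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for working with population-scaled recombination maps
    (rho = 4*Ne*r per base pair) estimated from patterns of linkage
    disequilibrium, as produced by LDhat/LDhelmet-style estimators.
    Provides readers and writers for per-SNP rate tables and BED interval
    sets, stitching of overlapping estimation windows, frequency-weighted
    map summaries and centimorgan anchoring, windowed map comparison and
    effective population size estimation, Lorenz curves and Gini
    coefficients of map heterogeneity, recombination hotspot calling with
    a flanking-background ratio and a randomization test of interval
    overlap, haplotype phasing quality control (pseudofemale construction,
    switch-error measurement and injection), site filtering with an exact
    Hardy-Weinberg test, ancestral allele polarization with a mutation
    matrix and its stationary distribution, per-gene diversity and
    divergence statistics at fourfold degenerate sites, and synthetic-data
    generators (including a sequential coalescent with recombination) that
    give every stage a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    IRanges,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
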