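Package: repscan
Title: Repeatability of Genomic Differentiation Landscapes Across Population Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed genome-scan statistics and cross-pair repeatability
    analyses for comparative population genomics. Computes per-window relative
    (Hudson F_ST, ratio of averages) and absolute (d_XY, callable-site
    normalised) differentiation from per-site allele counts, quantifies
    repeatability of differentiation landscapes across independent population
    pairs (correlation matrices, hypergeometric outlier-window overlap with
    z scores, peak-location permutation tests), relates repeatability to the
    speciation continuum with Mantel and partial Mantel tests, and models
    per-window repeatability counts as a function of genomic features (GC
    content, gene density, synonymous substitution rate, linkage
    disequilibrium, chromosome size class, position along the chromosome,
    centromere proximity) with Poisson regression. A synthetic multi-pair
    landscape generator with planted shared structure makes every stage of the
    pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
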