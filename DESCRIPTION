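Package: crisprtherm
Title: Thermal Distribution of CRISPR-Cas Abundance with Phylogenetic Controls
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing how per-genome CRISPR-Cas abundance
    (arrays, spacers, cas genes, cas gene clusters) varies along the
    optimal-growth-temperature axis of prokaryotes. Implements trait-table
    construction rules (annotation evidence filtering, temperature rounding,
    source-precedence merging), five-degree temperature binning, a ratio
    statistic contrasting mean abundance above and below a candidate
    temperature with a permutation null, Pagel's lambda phylogenetic-signal
    estimation, phylogenetic generalized least squares under the lambda
    model, sliding-window and temperature-category regression scans,
    penalized-spline smoothing with derivative-based localization of the
    transition temperature, and a seeded simulator of phylogenies and
    zero-inflated count traits with a sigmoidal step for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    mgcv,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    withr,
    optparse
Config/testthat/edition: 3
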