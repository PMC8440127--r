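Package: gecscan
Title: Genetic Exchange Community Analysis for Bacterial Pan-Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how phenotypes shape horizontal gene transfer
    within a bacterial family, following the genetic-exchange-community
    (GEC) approach developed for the Lactobacillaceae. From a strain
    phenotype table and ortholog-cluster membership the package filters
    strain-specific singletons, partitions clusters into core and
    accessory genomes by an n-percent conservation scan, computes the
    average sugar utilization (ASU) of each ortholog cluster and
    classifies clusters as generalist or specialist by the mean +/- 1 SD
    rule, profiles COG functional-category ratios with Welch t-tests and
    Benjamini-Hochberg correction, fits standardized multiple regressions
    of genome size and HGT-gene count on phenotypic and genomic features,
    and builds shared-ortholog networks over genomes with community
    extraction and cross-genus mixing summaries. A seeded synthetic-data
    generator with planted generalist/specialist structure and planted
    communities provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
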