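Package: episom
Title: Integrative SOM Portraits of DNA Methylation and Gene Expression Cohorts
Version: 0.1.0
Authors@R: person("Episom", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Self-organizing-map (SOM) portraiture of gene-centric molecular
    cohorts: batch-SOM training on promoter methylation beta values or
    log2 expression intensities, sample and class-mean portraits, spot-module
    segmentation of the metagene grid, gene-set Z-score (GSZ) enrichment with
    high/moderate/low stratification, sample similarity networks, and
    class-level coupling of methylation and expression changes for gene
    modules measured in unmatched cohorts. Ships a synthetic paired-cohort
    generator with planted co-methylation/co-expression modules and ground
    truth, so every pipeline stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
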