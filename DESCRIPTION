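Package: fstGBLUP
Title: Fixation-Index Weighted Genomic Relationship Matrices for Genomic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying SNP prioritization and weighting in genomic
    selection. Provides a forward-in-time breeding simulator (multi-generation
    random-mating history to establish linkage disequilibrium, Gamma-distributed
    QTL effects, truncation selection on estimated breeding values), per-locus
    Nei fixation-index (FST) scans contrasting phenotypic tail subpopulations,
    FST-proportional and group-budget SNP weighting schemes, weighted VanRaden
    genomic relationship matrices, GBLUP model fitting by average-information
    REML with breeding-value prediction for unphenotyped validation animals,
    and an orchestration layer that runs replicated weighting-scenario studies
    and summarizes variance components, prediction accuracy, bias, and the
    distribution of genomic relationships between training and validation sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
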