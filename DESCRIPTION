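Package: metapva
Title: Coupled Species Distribution and Stage-Structured Metapopulation
    Models for Harvested Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting the range and abundance of harvested plant
    species under combined climate-change, land-cover-change, and harvesting
    pressures. Couples presence/background species distribution models (GLM,
    regularized maxent-like logistic, random forest) evaluated by fivefold
    partitioning and combined as an AUC-weighted ensemble, with delta-change
    climate downscaling onto a fine baseline grid, habitat-patch delineation
    by a neighborhood distance rule, and replicated stochastic projection of
    a three-stage metapopulation with environmental stochasticity, ceiling
    density dependence, habitat-tracking carrying capacities, and quota-based
    harvest rules. Includes a synthetic-data module that generates landscapes,
    occurrences, climate series, land-cover masks, and stage-count tables
    with known ground truth so every stage of the pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    randomForest,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
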