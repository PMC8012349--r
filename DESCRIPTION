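Package: flavoromics
Title: Sensory-Metabolomic Inference for Fresh-Fruit Flavor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking consumer-panel sensory ratings to
    volatile, sugar and acid quantifications in fresh fruit. Implements
    panelist-adjusted least-squares means, per-period autoscaling of
    multi-batch chemical matrices, sensory-chemical correlation tables with
    multiplicity control, Bonferroni-filtered association networks with
    authority centrality, multiscale-bootstrap hierarchical clustering with
    AU/BP cluster support, per-period NIPALS partial least squares with
    VIP-based consensus selection of sweetness- and liking-enhancing
    volatiles, a sugar-independence test, a nested cross-validation
    benchmark of six regression learners against a sugars-and-acids
    baseline, Box-Cox phenotype normalization and single-marker QTL
    association, and a seeded synthetic-data generator with a ground-truth
    registry for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    glmnet,
    ranger,
    MASS,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    mixOmics,
    optparse
Config/testthat/edition: 3
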