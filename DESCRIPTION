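Package: migrascape
Title: Seasonal Species Distribution Ensembles and Migratory Corridor Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring seasonal habitat suitability and migratory
    corridors from presence-only occurrence records and monthly environmental
    rasters. Fits four presence-background species distribution models
    (climate-envelope BIOCLIM, logistic GLM with quadratic terms, a
    MaxEnt-style penalized exponential model, and random forest), evaluates
    them by AUC and the True Skill Statistic (TSS), combines them into a
    TSS-weighted ensemble, and infers corridors between seasonal ranges by
    three complementary methods: least-cost-path density on a conductance
    graph, circuit-theory current maps, and 95th-percentile suitability
    masks, with a consensus overlap. Includes spatial autocorrelation
    statistics (Moran's I, Geary's C) with permutation tests, paired
    distance-increase tests, occurrence cleaning and spatial thinning, a
    pairwise-correlation predictor screen, and a synthetic-data generator
    with a known seasonal niche and planted corridor for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    glmnet,
    randomForest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
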