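Package: netpharm
Title: Network-Pharmacology Target Prioritization with Clique-Centrality
    Hubs, Enrichment and Ensemble Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for prioritizing candidate drug targets from
    gene lists and protein-protein interaction (PPI) networks: target-list
    ingestion and intersection, PPI node-topology profiling including
    maximal clique centrality (MCC) hub ranking, hypergeometric
    over-representation analysis with Benjamini-Hochberg correction,
    a tree-ensemble machine-learning priority score mapped to a 0-15 scale,
    docking-energy table summarization, and multi-evidence rank fusion.
    Seeded synthetic-data generators emulate every input so the full chain
    is testable offline. Assay calculators implement common wet-lab
    quantification formulas (wound-healing rate, 2^-ddCt fold change,
    MDA and CAT kit formulas, standard-curve interpolation).
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    randomForest,
    stats,
    tools,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
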