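Package: fruitFBA
Title: Constraint-Based Modeling of Fruit Ripening Metabolism
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constraint-based (flux balance) analysis of climacteric fruit
    ripening metabolism. Parses curated tab-delimited reaction tables with
    gene-protein-reaction (GPR) rules into an S4 metabolic network, applies a
    maintenance-only ripening constraint scheme (NGAM ATP demand, capped
    reserve mobilization, blocked bypass pools), maximizes a composite
    ripening-quality sink objective by linear programming, integrates
    differential gene-expression contrasts as soft per-reaction flux
    penalties, and identifies regulatory lever reactions that must stay
    metabolically active despite transcriptional downregulation. Ships a
    reduced reference model of peach mesocarp ripening and seeded synthetic
    expression contrasts so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Metabolomics, Network, SystemsBiology, GeneExpression
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'equation.R'
    'fba.R'
    'fruitFBA-package.R'
    'gpr.R'
    'growth.R'
    'levers.R'
    'model-io.R'
    'model-methods.R'
    'reference-model.R'
    'scenarios.R'
    'simplex.R'
    'weights.R'
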