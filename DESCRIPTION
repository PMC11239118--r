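Package: tetragap
Title: Phylogeny-Informed Trait Imputation and Missing-Data Bias Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to fill gaps in species trait tables with phylogeny-informed
    multiple imputation (gradient-boosted trees combined with predictive mean
    matching over phylogenetic eigenvector filters), to test whether attributes
    share missing data using checkerboard C-score null models, and to quantify
    how imputation-based gap filling shifts clade- and assemblage-level trait
    summaries. Includes a synthetic-data generator for ultrametric clades with
    nested taxonomy, Brownian-motion body size, threshold-model binary traits,
    and controlled MCAR, MAR and MNAR missingness with shared gaps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
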