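Package: gemkit
Title: Constraint-Based Metabolic Modelling with Multi-Omics Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-scale metabolic models (GEMs): a data model with
    readers and writers for SBML Level 3 + FBC and the yeast-GEM YAML dialect,
    gene-protein-reaction (GPR) rule evaluation, mass and charge balance
    auditing, and standard-transformed Gibbs energy bookkeeping. Linear
    programming analyses include flux balance analysis (FBA), parsimonious FBA,
    hit-and-run flux sampling, single and double gene deletion with synthetic
    lethality classification, and substrate-usage screening. Omics integration
    covers GIMME context-specific model extraction from expression profiles,
    strain-specific models from knockout fold-changes with winsorized bound
    scaling, nitrogen-source preference scoring, protein regulation
    coefficients from paired flux and proteome series, and a kernel-PCA plus
    classifier harness for condition and gene-function prediction. A
    deterministic synthetic-data module generates a small test network with
    planted ground truth so every stage is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    yaml,
    xml2,
    stats,
    utils,
    e1071,
    randomForest,
    nnet,
    class,
    kernlab
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
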