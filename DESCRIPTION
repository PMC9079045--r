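Package: qsarflow
Title: Random-Forest QSAR Modelling of Bioactivity Data with
    Substructure Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end quantitative structure-activity relationship
    (QSAR) workflow for ChEMBL-style bioactivity tables: curation of raw
    IC50 records into one pIC50 value per unique desalted structure,
    SMARTS-based substructure count and presence fingerprints, Lipinski
    rule-of-five profiling, descriptor preprocessing (zero-variance and
    correlation filtering, autoscaling), repeated 70/30 data splits,
    random-forest regression with grid tuning and Gini-importance feature
    ranking, and a validation battery comprising 10-fold cross-validation,
    Y-scrambling, Golbraikh-Tropsha acceptability thresholds, the Eriksson
    chance-correlation margin, a PCA bounding-box applicability domain,
    and censored-label external accuracy. Includes a synthetic-data
    generator with ground-truth ledgers so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    ranger,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
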