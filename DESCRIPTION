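Package: mpmindex
Title: Microbiome Protein Metabolism Index from Functional Metagenomic and
    qPCR Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the Microbiome Protein Metabolism Index (MPMI) of
    broiler cecal microbiomes from KEGG-Orthology-annotated shotgun
    metagenomic gene counts, together with the companion analyses a
    production trial needs: KO-to-EC regrouping and internal normalization
    of functional profiles, random-forest feature ranking with local
    Fisher discriminant embedding of treatment groups, a targeted
    qPCR estimator of the index (qMPMI) with per-primer-set log-linear
    calibration, growth-performance indices (body weight gain, corrected
    feed conversion ratio, European Poultry Efficiency Factor), and a
    seed-deterministic synthetic-data generator that emulates the
    sequencing, qPCR plate, and pen-record inputs so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Metagenomics, Microbiome, Classification, Sequencing,
    FunctionalPrediction
RoxygenNote: 7.3.3
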