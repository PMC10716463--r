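Package: braintme
Title: Immune Ecosystem Characterization for Brain Tumor Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Procedures for characterizing tumor immune ecosystems from
    single-cell and bulk transcriptomics: tissue-preference odds ratios with
    Fisher exact tests, two-run clustering with mini-cluster purging,
    cross-platform random-forest transfer of microglia versus bone-marrow-derived
    macrophage labels, cross-dataset informative-gene selection with
    Davies-Bouldin cluster-number choice, marker-pathway determination,
    single-cell-derived gene signatures (scFes) including tumor
    immune-recruitment features, and immune-stromal-tumor archetype discovery
    on bulk cohorts with projection to external data and survival association.
    A synthetic-data module generates multi-platform single-cell datasets and
    pseudo-bulk cohorts with planted structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    randomForest,
    ape,
    survival,
    limma,
    fgsea,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
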