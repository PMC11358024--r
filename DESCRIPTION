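Package: transdep
Title: Translational Dependency Mapping from Expression-Predicted Gene Essentiality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Learns expression-based elastic-net models of gene essentiality
    from CRISPR-screened cell-line cohorts and transposes them onto aligned
    tumor, xenograft and healthy-tissue transcriptomes to build translational
    dependency maps. Includes contrastive-PCA transcriptional alignment with
    tumor-purity diagnostics, NormLRT scoring of strongly selective
    dependencies, lasso-based synthetic-lethality discovery with
    mutual-exclusivity and paralog filters, genetic-interaction scoring of
    multiplexed dual-knockout CRISPR screens, survival and drug-response
    association, and tumor-versus-healthy tolerability contrasts. Synthetic
    cohort generators with exported planted ground truth make every stage
    testable without consortium downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    survival,
    MASS,
    edgeR,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
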