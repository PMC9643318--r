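Package: repurposeBM
Title: Multiplexed Drug Repurposing for M2-Macrophage-Associated Bone
    Metastases of Castration-Resistant Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for signature-reversal drug repurposing
    against the bone-metastatic, M2-macrophage-enriched phenotype of
    castration-resistant prostate cancer. Provides differential-expression
    gene-set selection with cell-type correlation screens, consensus rank
    aggregation of drug lists from multiple signature-reversal sources,
    composite (activity/functional/structural) drug scoring, Tanimoto/Ward
    chemical redundancy clustering with representative selection, a signed
    bipartite compound-gene network criticality score, drug-sensitivity
    filtering with KNN imputation and ridge expression-response models,
    binding-energy to inhibition-constant conversion, and trajectory
    statistics (dynamic cross-correlation, RMSD, RMSF, radius of gyration).
    Seeded synthetic-data generators emulate every input so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
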