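Package: cartx
Title: Transcriptome and Regulatory-Network Analysis for Paired CAR-T Bone-Marrow Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for paired pre-/post-therapy bulk transcriptome
    cohorts without biological replicates, as arises in longitudinal CAR-T
    bone-marrow studies: FPKM/TPM quantification and expression filtering,
    per-patient paired fold-change differential expression for genes and
    miRNAs, weighted gene co-expression module detection (soft-threshold
    adjacency, topological overlap, eigengenes), Fisher-exact gene-set
    enrichment, marker-based immune-cell composition estimation, and assembly
    of heterogeneous miRNA-TF-gene(-lncRNA-pathway) regulatory networks.
    Includes a synthetic-cohort generator with planted ground truth (modules,
    differential expression, regulatory edges, cell-type mixtures) so every
    stage can be validated end to end without access to deposited sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    fgsea,
    igraph,
    jsonlite,
    mclust,
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
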