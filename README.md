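# cartx

Transcriptome and regulatory-network analysis for paired CAR-T
bone-marrow cohorts.

## The problem

Longitudinal CAR-T studies profile the bone marrow of a few patients
immediately before infusion (D0) and about two weeks after (D14) by bulk
RNA-seq and miRNA-seq — one library per patient and timepoint, no
biological replicates. Analyzing such cohorts requires a specific
toolkit: expression-unit computation and filtering (FPKM > 1 for genes,
TPM > 10 for miRNAs, strict), per-patient paired fold-change
differential expression (no dispersion estimate is possible with n = 1
pairs), weighted gene co-expression modules (unsigned adjacency
|r|^β, topological overlap TOM, average-linkage clustering, module
eigengenes), Fisher-exact gene-set over-representation, marker-based
immune-cell composition, and the assembly of heterogeneous
miRNA–TF–gene(–lncRNA–pathway) regulatory networks from curated
regulator→target tables.

`cartx` implements this pipeline as a tested R package. Its
distinguishing feature is a **synthetic-cohort generator with planted
ground truth** — module memberships, treatment shifts, repression edges,
cell-type mixtures — so every stage can be validated end to end without
access to deposited patient data. The generator is first-class, tested
code: expression follows a latent-factor model
`x = base + loading × factor(sample) + shift × 1[post] + repression + noise`
on the log2 scale, with module factors drawn orthogonal to each other and
to the treatment contrasts, exponentiated and rounded to counts.

Core statistics, in the field's standard notation:

- `FPKM_gs = 1e9 · C_gs / (N_s · L_g)`; TPM rescales `C_gs / L_g` to a
  column sum of 1e6.
- `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
  `a_ij = |r_ij|^β`.
- `VIP_j = sqrt(p · Σ_a SS_a (w_aj/‖w_a‖)² / Σ_a SS_a)` from NIPALS
  PLS-DA (`mean(VIP²) = 1`).
- Correlation p-values from `t = r·sqrt(n−2)/sqrt(1−r²)` on n−2 df;
  enrichment from the one-sided hypergeometric tail `P(X ≥ k)` with BH
  FDR.

## Worked example

```r
library(cartx)

cohort <- generate_cohort(default_scenario(seed = 1))
gene_fpkm <- fpkm(cohort$counts, cohort$annotation)
expressed <- filter_expressed(gene_fpkm, threshold = 1)
nrow(expressed)
#> 602                      # all simulated genes pass the FPKM > 1 filter

manifest <- run_pipeline(list(seed = 1, outdir = "cartx_out"))
state <- attr(manifest, "state")

table(state$modules$module)
#>      blue     brown     green       red turquoise    yellow
#>       113       110       105        54       113       107
mclust::adjustedRandIndex(state$modules$module,
                          cohort$truth$module_of[state$modules$feature_id])
#> 0.829                    # five planted modules recovered; "red" is a
                           # treatment-structured background cluster

head(state$important_mirnas, 3)
#>   feature_id direction
#> 1     mir018        up
#> 2     mir019        up
#> 3     mir039      down

state$network
#> <regulatory_network> 31 nodes, 35 edges
#>    gene   miRNA pathway      TF
#>      16       6       7       2
#> gene_pathway mirna_target
#>           17           18

head(state$crosstalk, 3)
#> [1] "gene0351" "gene0019" "gene0038"
```

Reading the output: six miRNAs are differential with a consistent
direction in every remissive patient; their targets that were themselves
called differential form the network's gene layer (two of them are
transcription factors), and the crosstalk genes connect at least two
distinct pathways. The 0.829 adjusted Rand index measures agreement
between detected module labels and the planted memberships over all 602
features. Every file the pipeline writes is listed, with md5 checksums,
in `cartx_out/manifest.tsv`; rerunning with the same seed reproduces the
checksums exactly.

The methods vignette (`vignettes/cartx-methods.Rmd`) documents the
model, every tunable parameter with its default and rationale, the
numerical conventions, and known limitations.

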