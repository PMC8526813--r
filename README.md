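# stromascope

Tools for dissecting the **stromal microenvironment of medulloblastoma**
(and similar subgrouped tumour cohorts) from bulk and single-cell
transcriptomics. Medulloblastoma's four molecular subgroups (WNT, SHH,
group 3, group 4) differ in how much non-neoplastic stroma they carry;
`stromascope` quantifies that admixture and traces the receptor/ligand
signalling that may drive it, for computational biologists who have a
genes × samples expression matrix and subgroup labels.

The pipeline:

1. **Signature scoring** — a per-sample, rank-based enrichment score.
   For sample *j*, genes are ranked by expression and the walk
   ES = Σᵢ [P_in(i) − P_out(i)] is accumulated, where P_in weights
   in-signature genes by rankᵅ (α = 0.25) and P_out steps uniformly
   through the remaining genes. Applied to stromal and immune signatures
   this is the ESTIMATE-style stromal/immune score (`ssgsea_score`).
   Scaled-average signature scores and module meta-genes (PC1 of a
   module) are also provided.
2. **Driver/suppressor screen** — Welch t-test of a subgroup against the
   pooled rest plus per-gene Pearson correlation with the stromal score.
   A receptor/ligand gene with |log₂FC| > 1, r > 0.2 and both p < 0.05
   (up in the stroma-enriched subgroup or down in the suppressed one) is
   a *stroma-driver*; the mirror image is a *stroma-suppressor*
   (`classify_associates`).
3. **Network centrality** — thresholded Pearson co-expression network
   over the associates (|r| ≥ 0.6 bulk / 0.2 single-cell, p < 0.05) with
   Wasserman–Faust component-scaled closeness centrality,
   C(v) = (R/(n−1))·(R/D) (`build_network`).
4. **Single-cell stroma activity** — per-cell counts of expressed
   associates; cells with > 5 are *stroma-active*, < 2 *stroma-inactive*;
   rank-sum markers, a metastasis contrast, and a gene-counts
   developmental-potential score rank-scaled to [0, 1]
   (`count_associates`, `classify_state`, `dev_potential`).
5. **Synthetic cohorts** — seeded generators that plant subgroup-specific
   stromal fractions, driver genes and a per-cell activity gradient, so
   every stage is testable with ground truth (`generate_bulk`,
   `generate_sc`).

See `vignettes/stromal-microenvironment.Rmd` for the full model
description and design rationale.

## Worked example

```r
library(stromascope)

b <- generate_bulk(bulk_sim_config(seed = 1))     # 2000 genes x 200 samples
scores <- score_table(b$matrix, b$signatures, method = "ssgsea")
round(tapply(scores$stromal, b$annotation$subgroup, mean), 1)
#> Group3 Group4    SHH    WNT
#>  200.1  253.3  399.4  273.4
```

The SHH-like subgroup is stroma-enriched and the group-3-like subgroup
suppressed, as planted (high- vs low-mean Beta stromal fractions).

```r
enr <- screen_subgroup(b$matrix, b$annotation, "SHH", scores)
sup <- screen_subgroup(b$matrix, b$annotation, "Group3", scores)
assoc <- classify_associates(enr, sup, b$rl, exclude = b$signatures)
table(assoc$class, assoc$role)
#>          ligand receptor
#>   driver     15       15

net <- build_network(b$matrix, assoc, r_min = 0.6)
net
#> gene_network: 30 nodes, 308 edges (|r| >= 0.6 , p < 0.05 )
head(net$nodes[order(-net$nodes$closeness), c("gene", "class", "closeness")], 3)
#>          gene  class closeness
#> 18 gene_00218 driver 1.0000000
#> 28 gene_00228 driver 0.9666667
#> 5  gene_00205 driver 0.9062500
```

All 30 planted drivers — and nothing else — are recovered; the densely
co-regulated drivers have near-maximal closeness. A closeness of 1 means
the gene is directly connected to every other associate.

A YAML-driven end-to-end run (bulk + single cell, all outputs + manifest
written to `outdir`):

```r
run_all(read_run_config(system.file("extdata", "run_template.yaml",
                                    package = "stromascope")))
```

or from a shell via the thin CLI:

```sh
Rscript $(Rscript -e 'cat(system.file("exec", "stromascope", package = "stromascope"))') \
    run --config run.yaml
```

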