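---
title: "Methods: quantifying the stromal microenvironment of medulloblastoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the stromal microenvironment of medulloblastoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromascope)
```

## The analysis in one paragraph

Medulloblastoma comprises four molecular subgroups (WNT, SHH, group 3,
group 4) that differ not only in their tumour cells but in their
microenvironment: the non-neoplastic stromal and immune fractions mixed
into every bulk sample. `stromascope` quantifies that stromal admixture
per sample with a rank-based signature score, asks which receptor and
ligand genes could mediate it (genes both differentially expressed in a
stroma-enriched or stroma-suppressed subgroup *and* correlated with the
stromal score), maps the co-expression structure of those
*stroma-associates* as a thresholded correlation network ranked by
closeness centrality, and then moves to single cells, where the number of
stroma-associates a cell expresses defines a *stroma-active* to
*stroma-inactive* gradient that is compared against a gene-counts proxy
for developmental potential.

## Signature scoring

**ssGSEA-style enrichment (`ssgsea_score`).** For one sample, genes are
ranked by expression (ties receive the average rank) and the ranking is
walked from the most to the least expressed gene. Writing $r_g$ for the
rank statistic and $S$ for the signature, the walk accumulates

$$\mathrm{ES} = \sum_{i=1}^{N} \left[ P_{\mathrm{in}}(i) -
P_{\mathrm{out}}(i) \right], \qquad
P_{\mathrm{in}}(i) = \frac{\sum_{g \in S,\, \mathrm{pos}(g) \le i} r_g^{\alpha}}
     {\sum_{g \in S} r_g^{\alpha}}, \quad
P_{\mathrm{out}}(i) = \frac{\#\{g \notin S,\, \mathrm{pos}(g) \le i\}}{N - |S|}.$$

The exponent $\alpha$ weights highly expressed genes; the default 0.25 is
the convention of the single-sample enrichment tools this score
reimplements. Because only within-sample ranks enter, the score is
invariant under any monotone transform of a sample's values and under
gene reordering — both properties are asserted in the test suite. Scores
are *not* normalised between samples; cross-cohort comparison is the
caller's responsibility.

**Scaled-average score (`scaled_average_score`)** z-scores each gene
across samples (zero-variance genes contribute 0) and reports the mean z
of the signature minus the mean z of all remaining genes — the standard
construction for stemness and cycling signatures in single-cell work.

**Module meta-gene (`metagene`)** is the first principal component of a
gene module's centred expression, the usual co-expression-module summary.
PC sign is inherently arbitrary; it is anchored so the meta-gene
correlates non-negatively with mean module expression, making output
deterministic. Module *detection* (soft-thresholding, topological
overlap, tree cutting) is out of scope; the package only evaluates given
modules.

## The driver/suppressor screen

Two screens are run against the pooled remainder of the cohort: one for
the stroma-enriched subgroup (SHH by default) and one for the
stroma-suppressed subgroup (group 3). Each is a per-gene Welch two-sample
t-test on the log2 matrix — the test is deliberately simple and
variance-robust for array-scale log data; no moderated/shrinkage
estimator is used — plus a per-gene Pearson correlation with the
full-cohort stromal score and its t-distribution p-value. Fold-change is
the difference of group means on the log2 scale, so the published linear
cutoff of 2 becomes $|\log_2\mathrm{FC}| > 1$.

`classify_associates` then labels a receptor/ligand gene a
**stroma-driver** when it is positively correlated with the stromal
score ($r > 0.2$, $p < 0.05$) and either up in the enriched subgroup or
down in the suppressed one ($|\log_2\mathrm{FC}| > 1$, $p < 0.05$), and
a **stroma-suppressor** under the mirrored conditions. All inequalities
are strict, matching the wording of the cutoffs. Genes in any excluded
signature (by default the stromal and immune panels themselves, which
would qualify trivially) are removed, as are genes with undefined
(constant-gene) correlation, and — when single-cell data is present —
genes detected in fewer than 1% of cells. Screen p-values are left
unadjusted by default because the screen's published criterion is on raw
p; a Benjamini–Hochberg column is available behind `adjust = TRUE`.
With a single shared correlation column the driver and suppressor
conditions are mutually exclusive; the conflict branch (drop with
warning) exists defensively for callers supplying screens correlated
against different scores.

## Correlation networks and closeness

`build_network` computes all-pairs Pearson correlations among the
associates and keeps an undirected edge when $|r| \ge r_{\min}$ (0.6 in
bulk, 0.2 in single cells, where correlations are weaker) and $p <
0.05$. Negative edges participate in the topology — anticorrelation is
still co-regulation — with the sign kept as an attribute.

Closeness centrality is computed on the unweighted thresholded topology.
Because the graphs can be disconnected, the Wasserman–Faust
component-scaled form is used: for a node $v$ reaching $R$ other nodes at
total hop distance $D$ in a graph of $n$ nodes,

$$C(v) = \frac{R}{n-1} \cdot \frac{R}{D},$$

which is 0 for isolates, lies in $[0,1]$, and equals 1 only for a node
adjacent to every other node of a connected graph. A
correlation-weighted variant (edge length $1-|r|$) is available via
`closeness_centrality(net, weighted = TRUE)`; it is not the default
because the thresholded-edge description the analysis follows defines no
weighting rule, and the unweighted reading is the simplest faithful one.
The component-scaling choice is recorded in the network object itself.

## Single-cell stroma activity and developmental potential

"Expressed" means normalised expression strictly greater than zero
throughout — library-size normalisation and log transform preserve
zeros, so this coincides with nonzero counts. `count_associates` tallies
expressed associates per cell by role; `classify_state` applies the
strict cutoffs (> 5 associates active, < 2 inactive, boundary counts
intermediate). The published wording defines states on driver counts and
plots ligands and receptors separately; the total count is the
classification default here, with `role = "ligands"`/`"receptors"`
selectable, because the role-specific choice is otherwise ambiguous.

Markers of active versus inactive cells come from a per-gene two-sided
Wilcoxon rank-sum test (normal approximation) with Benjamini–Hochberg
adjustment, markers being upregulated genes at adjusted $p < 0.05$; genes
below the 1% detection floor in both states are untested. The metastasis
contrast is a rank-sum test of per-cell associate counts grouped by the
tumour-level metastasis flag; since cells within a tumour are
pseudoreplicates, the per-tumour mean counts and a tumour-level test are
reported alongside the cell-level p-value.

`dev_potential` is a deliberately simplified gene-counts stemness proxy:
the number of detected genes per cell is correlated against every gene,
the `top_k = 200` most-correlated genes form a signature, and each
cell's mean signature expression is rank-scaled to $[0,1]$ (1 = least
differentiated). The published pipeline this emulates additionally
smooths scores across transcriptionally similar cells; that step is
omitted, the simplification is validated only against synthetic activity
gradients, and the score is never claimed to equal the original tool's
output on real data. The final rank step makes the score invariant to
per-cell monotone transforms that preserve detection and signature
ordering.

## What the synthetic cohorts emulate — and what they do not

The generator exists so every stage can be tested end to end with known
ground truth; its defaults are fixed study conditions, not tuning knobs.

**Bulk (`bulk_sim_config`).** 2,000 genes × 200 samples; subgroup
proportions 9.2 / 29.2 / 18.8 / 42.8% (WNT/SHH/group 3/group 4),
mirroring the discovery cohort's composition. Each sample draws a latent
stromal fraction from a subgroup-specific Beta — SHH high
(Beta(6,3)), group 3 low (Beta(2,7)), others intermediate — the simplest
bounded latent reproducing the stroma-enriched/suppressed contrast.
Stromal and immune signature genes (100 each) gain
`signature_coupling = 2` log2 units per unit latent fraction; 30 planted
receptor/ligand drivers gain `driver_log2fc = 1.5` in SHH plus
`driver_stroma_coupling = 3` times the centred stromal fraction; 60
further receptor/ligand genes carry no signal and form the
false-positive pool; residual noise is Gaussian with SD 1 on the log2
scale, array-like. With noise SD 1 and a latent-fraction SD near 0.2,
the coupling of 3 gives a per-gene population correlation with the
latent fraction around 0.5 — strong but realistic for a bona fide
microenvironment gene.

**Single cell (`sc_sim_config`).** 10 tumours × 300 cells × 2,000 genes.
Each tumour draws a mean activity (metastatic tumours from 0.5–0.75,
others 0.25–0.5, planting the metastasis direction); cells draw activity
around it from a Beta with concentration 8. Associate genes are detected
with probability $\mathrm{logit}^{-1}(6\,(a - 0.5))$; every other gene's
baseline detection logit shifts by `potential_coupling = 2` per unit
activity, so total detected-gene counts track the gradient. Detected
counts are negative-binomial (dispersion 2) shifted by one, then
library-normalised to 10,000 and log1p-transformed — the standard
single-cell normalisation.

Not emulated: batch effects, doublets, ambient RNA, gene-length/GC
biases, cell-type mixtures beyond the activity gradient, and any real
receptor-ligand biology (pairs are arbitrary). Passing recovery tests
therefore demonstrates that the pipeline's inference machinery is
correct and well-calibrated under its own assumptions, not that it would
recover biology from any particular real cohort.

## Numerical and validation choices

* All randomness flows from a single integer seed per generator call;
  identical config + seed reproduces identical bytes, and the pipeline
  manifest records MD5 hashes to make this checkable.
* Cohort percentages are rounded half-up to one decimal (plain `round()`
  banker's rounding would mis-report e.g. 16.25% as 16.2%).
* Zero-variance genes: z-score 0 in scaled averages, undefined (and
  excluded) in correlation screens, isolated nodes in networks, p = 1 in
  DGE when both group means coincide, p = 0 when exact separation.
* Validation problem sizes: oracle-equivalence tests use 20-gene × 3-
  sample matrices (enrichment walk) and random graphs up to 12 nodes
  (closeness), where brute-force oracles are exact and cheap; recovery
  tests run the full pipeline at the default 2,000 × 200 bulk and
  3,000-cell single-cell scale over 20 seeds.
* The tie order within the enrichment walk follows the stable order of
  the rank sort; with average ranks this matters only for exactly tied
  values, which continuous expression data essentially never produces.

## Known limitations

The package evaluates given signatures, modules and receptor-ligand
tables; it discovers none of them. The bulk screen's unadjusted p-values
follow the published criterion and will admit false positives at scale
if used outside the fold-change + correlation conjunction. The
developmental-potential score is a simplified proxy (see above). The
cell-level metastasis contrast inherits pseudoreplication from its
published design; use the reported per-tumour summary for inference.
Embeddings (UMAP/t-SNE) are accepted for plotting overlays elsewhere but
never computed here.
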