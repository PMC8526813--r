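# Fully-populated stromascope pipeline configuration.
# With `simulate: true` the input paths are ignored and a seeded synthetic
# cohort is generated instead (overrides under `bulk:` / `sc:`).

simulate: true
seed: 1
outdir: stromascope_out

# --- inputs (used when simulate: false) ---------------------------------
matrix_path: bulk_matrix.tsv          # genes x samples, log2, TSV
annotation_path: bulk_annotation.tsv  # sample_id, subgroup[, metastasis]
signatures_path: signatures.gmt       # must contain 'stromal' and 'immune'
rl_path: rl_pairs.tsv                 # ligand TAB receptor
sc_matrix_path: ~                     # optional genes x cells, log-normalised
sc_annotation_path: ~                 # cell_id, subgroup, tumour_id, metastasis

# --- thresholds ---------------------------------------------------------
fc: 2                  # linear fold-change cutoff (applied as |log2fc| > 1)
r_min: 0.2             # minimum |Pearson r| with the stromal score
alpha: 0.05            # significance level for every screen and edge test
r_min_network_bulk: 0.6   # bulk co-expression edge threshold
r_min_network_sc: 0.2     # single-cell co-expression edge threshold
active_min: 5          # stroma-active: cell expresses > 5 associates
inactive_max: 2        # stroma-inactive: cell expresses < 2 associates
sc_expressed_frac: 0.01   # drop genes detected in < 1% of single cells
ssgsea_alpha: 0.25     # rank-weight exponent of the enrichment walk
top_k: 200             # gene-counts signature size for the potential score

enriched_subgroup: SHH      # stroma-enriched target of the first screen
suppressed_subgroup: Group3 # stroma-suppressed target of the second screen
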