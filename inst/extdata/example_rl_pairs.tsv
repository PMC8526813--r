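gene_00011	gene_00012
gene_00013	gene_00014
gene_00015	gene_00012
gene_00016	gene_00017
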