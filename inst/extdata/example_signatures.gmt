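stromal	synthetic stromal signature (toy example)	gene_00001	gene_00002	gene_00003	gene_00004	gene_00005
immune	synthetic immune signature (toy example)	gene_00006	gene_00007	gene_00008	gene_00009	gene_00010
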