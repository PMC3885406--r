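quantity	value
total_genes	6462
cancer_genes	1347
disruptive_genes	803
disruptive_cancer_genes	188
total_utr_snvs	29290
mature_mirnas	2042
structure_candidate_snvs	472
mirts_candidate_snvs	490
overlap_snvs	48
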