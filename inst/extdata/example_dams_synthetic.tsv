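# synthetic example disease-mutation table (not real variants)
gene	protein_position	ref_aa	alt_aa	source_id	external_score
GENE1	12	R	W	SYNTH_VAR_001	0.98
GENE1	45	G	D	SYNTH_VAR_002	0.91
GENE1	77	L	P	SYNTH_VAR_003	0.45
GENE1	103	C	Y	SYNTH_VAR_004	0.99
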