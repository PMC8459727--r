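set_id	database	p_adj	nes
hsa03030	KEGG	0.004	2.31
R-HSA-69306	Reactome	0.012	2.05
WP466	WikiPathways	0.03	1.88
hsa00620	KEGG	0.02	1.64
R-HSA-70268	Reactome	0.01	-1.71
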