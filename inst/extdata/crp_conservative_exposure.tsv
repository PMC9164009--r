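SNP	effect_allele	other_allele	eaf	beta	se	pval	N
rs3093077	C	A	0.0716	0.21	0.018	1.89e-31	204402
rs1205	C	T	0.6899	0.18	0.01	1.95e-72	204402
rs1130864	A	G	0.327	0.13	0.008	2.23e-59	204402
rs1800947	C	G	0.9429	0.26	0.015	2.64e-67	204402
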