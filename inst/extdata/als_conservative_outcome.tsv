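SNP	effect_allele	other_allele	eaf	beta	se	pval	N
rs3093077	C	A	0.0716	0.0356	0.0272	0.1913	80610
rs1205	C	T	0.6899	-0.0109	0.0144	0.4501	80610
rs1130864	A	G	0.327	-0.0296	0.0146	0.04302	80610
rs1800947	C	G	0.9429	0.0178	0.033	0.5905	80610
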