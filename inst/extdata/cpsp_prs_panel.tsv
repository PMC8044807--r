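snp	major_allele	minor_allele	risk_allele	gene	weight	p_linear	chrom	pos	maf
rs62069959	G	A	G	PRKCA	2.299	0.001	17	64318923	0.196
rs7125415	G	A	A	DRD2	1.657	0.034	11	113000000	0.126
rs61131185	A	G	G	ATXN1	1.524	0.011	6	16623387	0.322
rs12665284	G	A	G	ATXN1	1.481	0.041	6	16626066	0.146
rs202146909	A	G	A	KCNJ3	1.414	0.042	2	156000000	0.193
rs493352	G	A	G	ATXN1	1.242	0.031	6	16744169	0.488
rs9754467	A	G	A	CACNG2	1.166	0.032	22	37019059	0.222
rs12198202	A	G	A	ATXN1	1.064	0.005	6	16679771	0.424
rs11079653	T	A	T	PRKCA	0.98	0.011	17	64352329	0.202
rs2850125	G	A	G	KCNJ6	0.936	0.046	21	39130114	0.456
rs9914723	G	A	A	PRKCA	0.917	0.004	17	64716397	0.196
rs7220480	A	G	G	PRKCA	0.857	0.048	17	64686679	0.406
rs2891519	G	A	A	KCNK3	0.835	0.008	2	26954991	0.220
rs200369418	A	C	A	PRKCA	0.816	0.028	17	64762496	0.500
rs3812204	G	A	A	ATXN1	0.789	0.038	6	16698022	0.345
rs4716060	C	A	A	ATXN1	0.772	0.038	6	16310456	0.345
rs6459476	A	C	C	ATXN1	0.736	0.048	6	16618187	0.348
rs227912	A	G	A	PRKCA	0.678	0.049	17	64610729	0.246
rs744214	G	A	G	PRKCA	0.634	0.017	17	64334856	0.316
rs1992701	G	A	A	KCNJ3	0.584	0.047	2	156000000	0.453
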