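gene	chrom	pos	ref	alt	rsid	cdna	protein	source	classification	mode	phenotype
LDLR	chr19	11102500	A	C	rs1064793799	c.313+3A>C	.	ClinVar	P	dominant	Familial Hypercholesterolemia
LDLR	chr19	11105800	A	G	rs771019366	c.269A>G	p.Asp90Gly	ClinVar	P/LP	dominant	Familial Hypercholesterolemia
LDLR	chr19	11111200	A	G	rs758194385	c.1691A>G	p.Asn564Ser	ClinVar	LP	dominant	Familial Hypercholesterolemia
LDLR	chr19	11120400	T	G	rs879254809	c.1154T>G	p.Leu385Arg	ClinVar	LP	dominant	Familial Hypercholesterolemia
ABCG5	chr2	43820000	C	T	rs199689137	c.1336C>T	p.Arg446Ter	ClinVar	P	recessive	Sitosterolemia 1
ABCG8	chr2	43860000	G	A	rs137852988	c.1720G>A	p.Gly574Arg	ClinVar	P/LP	recessive	Sitosterolemia 2
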