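rsid	chrom	pos	effect_allele	other_allele	beta
rs629301	chr1	109275684	T	G	0.145
rs1367117	chr2	21044073	A	G	0.102
rs4299376	chr2	43845437	G	T	0.085
rs1564348	chr6	160578860	C	T	0.068
rs1800961	chr20	44413724	C	T	0.187
rs3757354	chr6	16127245	C	T	0.068
rs11220462	chr11	126243952	A	G	0.119
rs8017377	chr14	24407084	A	G	0.06
rs6511720	chr19	11091630	G	T	0.17
rs429358	chr19	44908684	C	T	0.136
rs7412	chr19	44908822	C	T	0.255
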