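chr19	11089361	11133820	LDLR
chr2	21001428	21044073	APOB
chr1	55039474	55064852	PCSK9
chr1	25543499	25590000	LDLRAP1
chr2	43812471	43838865	ABCG5
chr2	43838886	43878700	ABCG8
chr10	89213568	89252000	LIPA
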