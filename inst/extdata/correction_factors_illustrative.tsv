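med_class	factor
unspecified	1.43
statin_low	1.33
statin_moderate	1.54
statin_high	1.82
statin_ezetimibe	2
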