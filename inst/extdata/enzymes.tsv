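name	motif	cut_offset
DdeI	CTNAG	1
EcoRI	GAATTC	1
HinfI	GANTC	1
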