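gene	mirna	start	end	score
PRKACB	hsa-miR-200c-3p	841	862	-0.45
PRKACB	hsa-miR-200c-3p	2399	2418	-0.88
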