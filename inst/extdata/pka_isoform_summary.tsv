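gene	group	identity	similarity	utr_length_bp	n_mirnas
PRKAR1A	regulatory	1	1	2318	55
PRKAR1B	regulatory	0.81	0.91	680	3
PRKAR2A	regulatory	0.35	0.5	925	28
PRKAR2B	regulatory	0.34	0.48	2228	48
PRKACA	catalytic	1	1	1415	10
PRKACB	catalytic	0.93	0.95	3191	68
PRKACG	catalytic	0.83	0.92	497	8
CFL1	cofilin	1	1	520	5
CFL2	cofilin	0.81	0.9	2483	91
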