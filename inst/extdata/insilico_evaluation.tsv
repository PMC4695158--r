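gene	votes	n_sites	mirsvr_score
CFL2	6/6	1	-1.26
FSCN1	3/6	1	-1.17
GPX4	1/6	0	0
LIMK1	2/6	1	-0.03
MARCKS	6/6	3	-2.56
PRKAR1A	3/6	1	-0.49
SEC23A	6/6	3	-2.61
TBCE	1/6	0	0
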