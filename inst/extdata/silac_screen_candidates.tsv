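gene	uniprot	coverage_rep1	log2_fc_rep1	coverage_rep2	log2_fc_rep2	combined_p
CFL2	Q9Y281	24.7	-1.06	36.7	-0.96	0.000457
FSCN	Q16658	2	-1.03	4.7	-0.45	0.00354
GPX4	P36969	5.6	-0.47	5.6	-0.77	0.0571
LIMK1	P53667	2.2	-0.78	2.2	-0.95	0.0109
MARCKS	P29966	20.8	-0.51	20.8	-1.04	0.00513
PRKAR1A	P10644	8.9	-0.83	12.3	-0.68	0.00139
SEC23A	Q15436	5.1	-1.57	6.1	-0.62	6.25e-06
TBCE	Q15813	2.3	-1.03	4.6	-0.44	0.00555
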