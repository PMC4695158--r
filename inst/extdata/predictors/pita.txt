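CFL2
MARCKS
PRKACB
PRKAR1A
SEC23A
TBCE
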