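CFL2
GPX4
MARCKS
PRKACA
PRKACB
SEC23A
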