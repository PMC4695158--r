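>PRKACA synthetic stand-in, not the UniProt sequence
KSYSFAVYTCQDITILLGKSDKYWQGWPIENRDLHLRVGRWQIAGQHSFMHYTYCRWYFPMWETQAEFLCHRKSYLVPCEPCQGMTYWQEASMIYLVTWWRMGKNELNNNFVIYAYETWGYVWGIRRFGTVKFMVTDMGESNISVFCTAMHLYRRAEFDMHFAVAKSNKRVNLWTFEQHLHQNCSWTTKFPRNRWMPQEVSTPDMHYTTKYVNGSYEKDPADCPWFPFSTSFPYCWSHHDKEKKWNIVEMYDIFYFFRMWWGSIVVGDRGCQLQLWQDDFNWGLEHMPSGIITIKRWIIWGLNGSPGERPLHGTMGVPGRVCRSLPQGWSFGRATFIQNVTANNVFKAVH
>PRKACB synthetic stand-in, not the UniProt sequence
KCYSMAVYTCQDFTIDDGVMDKYWQCWPIENRAKHLRVGRWQIAGQHSFMHYTYCRWYFPMEEGQAEFLCHRKSYLVPCEPCQGKTDGQEAYMIYLVTWWAMGKNELNLNFVSIAKENHGYVWGPCRFGTVKFMVTDMGESNIVVFCQAMHLYRRAEWDMLFAVAYSQKRENLVTQEQHLHQNCSETTKFPRNRWMPQEVSTPDMHVTTKYVNGSKEPDPADCPWKPRSTSFPYCWSHHDKEKKWNNVETYDIFYFFRMWWGSIVVMDRGQQLQMWQDDFNWGLEHMPSGIITHKRWTIWGINGNSGERPLHGTMGVTGRVCRALPQGWSFGRQTQYKGVTPNNPFKCVH
>CFL1 synthetic stand-in, not the UniProt sequence
RHIHSARPISAFMDWAMAFIGMTMAGKACYWLTANRYWLYYINTEWHVHNNVYTYNAYCYKHMWVWHVMSTFSKQHVITEAMGSLDMAREKMICVEDLHAEQCDTHCTMEPRIVSWMTGKKVRVVYEMNKETFQEVWNGCGPWKCLLCHNHEFRNIIDGIMMAYSCLMDV
>CFL2 synthetic stand-in, not the UniProt sequence
RAWQSFRYISAFMDWARWFICDMDAGLACYALTANRYWPYYMNTEHHVENNVYEYNCYCYKHMYVIHWMFTSSKQGLIPEFRGSGDMPDEKQICYEDMHATQEVTHCTMEPRFVSWMTWKKVRQNYEHNMETFQEVWNGRGDESCHLCHFHEDRNIIDEIMMAMSCLNDV
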