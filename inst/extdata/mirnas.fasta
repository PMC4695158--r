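>hsa-miR-200a-3p
UAACACUGUCUGGUAACGAUGU
>hsa-miR-200b-3p
UAAUACUGCCUGGUAAUGAUGA
>hsa-miR-200c-3p
UAAUACUGCCGGGUAAUGAUGGA
>hsa-miR-141-3p
UAACACUGUCUGGUAAAGAUGG
>hsa-miR-429
UAAUACUGUCUGGUAAAACCGU
>hsa-miR-590-3p
UAAUUUUAUGUAUAAGCUAGU
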