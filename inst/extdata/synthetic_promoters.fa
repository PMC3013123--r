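>focused tss=30
GCCACATCCCGCCCCGGTGCTCGGCAATATATTTAGCGGCTCGGGCCGCCCTGGGGCGGG
>flat tss=30
GCCACATCCCGCCCCGGTGCTCGGCCCGTGGCGCAGCGGCTCGGGCCGCCCTGGGGCGGG
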