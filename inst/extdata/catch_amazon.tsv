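species	tonnage
Jaraqui	16,086
Curimata	6,934
Pacu	6,543
Piramutaba	3,794.5
Tambaqui	2,664.5
Matrinxa	2,394.5
Sardinha	2,316
Mapara	2,292
Tucunare	2,269.5
Pirapichinga	1,928
Others	13,084
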