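species	tonnage
Mackerel	5,405.35
Sardine	2,725.52
Blue whiting	2,042.49
Tuna	1,727.15
Hake	1,625.82
Atlantic mackerel	482.35
Frog-fish	298.25
Conger eel	268.17
Red mullet	157.80
Megrim	136.10
Others	1,696.80
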