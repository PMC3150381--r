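species	tonnage
Sardine	13,188
Anchovy	4,184
Mackerel	1,659
Hake	1,331
Atlantic mackerel	616
European seabass	279
Gilt-head bream	248
Chub mackerel	106
Blue whiting	14
Black seabream	9
Others	8,825
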