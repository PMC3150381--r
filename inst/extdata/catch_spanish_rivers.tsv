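species	tonnage
Brown trout	348.6
Atlantic salmon	9.2
European eel	8
Others	28.4
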