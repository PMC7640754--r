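subset,n
flower,12
fruit,3
leaf,10
plant,13
herb,24
monocot,24
woody,7
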