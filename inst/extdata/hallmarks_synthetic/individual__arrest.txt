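G00041
G00042
G00043
G00044
G00045
G00046
G00047
G00048
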