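G00065
G00066
G00067
G00068
G00069
G00070
G00071
G00072
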