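G00082
G00059
G00071
G00068
G00079
G00042
G00055
G00066
G00048
G00043
G00097
G00098
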