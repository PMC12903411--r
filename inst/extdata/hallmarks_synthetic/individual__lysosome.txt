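G00073
G00074
G00075
G00076
G00077
G00078
G00079
G00080
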