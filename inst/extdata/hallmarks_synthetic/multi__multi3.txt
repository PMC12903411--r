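G00055
G00046
G00056
G00062
G00061
G00044
G00051
G00078
G00066
G00063
G00101
G00102
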