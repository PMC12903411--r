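G00049
G00050
G00051
G00052
G00053
G00054
G00055
G00056
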