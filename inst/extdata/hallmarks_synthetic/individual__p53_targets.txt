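G00089
G00090
G00091
G00092
G00093
G00094
G00095
G00096
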