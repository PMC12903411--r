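G00064
G00080
G00062
G00087
G00048
G00066
G00052
G00060
G00095
G00071
G00099
G00100
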