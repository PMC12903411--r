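G00057
G00058
G00059
G00060
G00061
G00062
G00063
G00064
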