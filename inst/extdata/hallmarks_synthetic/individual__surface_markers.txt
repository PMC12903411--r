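G00081
G00082
G00083
G00084
G00085
G00086
G00087
G00088
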