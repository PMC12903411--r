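G01764
G01334
G00518
G00698
G01977
G00524
G01378
G00311
G01601
G01963
G00755
G02198
G01639
G00243
G02388
G00838
G02539
G01127
G01629
G00352
G00350
G00970
G00467
G02296
G02109
G01672
G02488
G01913
G00688
G00405
G00451
G00032
G00947
G00295
G00892
G01141
G02182
G00858
G02382
G02128
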