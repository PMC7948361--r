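hexamer	freq
AAUAAA	0.5950
AUUAAA	0.1990
UAUAAA	0.0740
AAGAAA	0.0630
AAUAUA	0.0540
AGUAAA	0.0011538462
AAUACA	0.0011538462
CAUAAA	0.0011538462
GAUAAA	0.0011538462
AAUGAA	0.0011538462
UUUAAA	0.0011538462
ACUAAA	0.0011538462
AAUAGA	0.0011538462
AAUAAU	0.0011538462
AACAAA	0.0011538462
AUUACA	0.0011538462
AUUAUA	0.0011538462
AAUAAG	0.0011538462
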