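2i_1: 2i
2i_2: 2i
2i_3: 2i
serum_1: serum
serum_2: serum
serum_3: serum
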