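hu,sp
-970,0
-479,0.481
9.5,1.00
118,1.081
127,1.091
292,1.258
474,1.431
673,1.622
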