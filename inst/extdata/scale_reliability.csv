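term,label,l,m,u
VL,Very low,0,0,0.3
L,Low,0.1,0.3,0.5
M,Medium,0.3,0.5,0.7
H,High,0.5,0.7,0.9
VH,Very high,0.7,1,1
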