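term,label,l,m,u
VL,Very low,0,1,2
L,Low,1,2,3
ML,Medium low,2,3.5,5
M,Medium,4,5,6
MH,Medium high,5,6.5,8
H,High,7,8,9
VH,Very high,8,9,10
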