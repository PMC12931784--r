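term,label,l,m,u,ci
EI,Equally important,1,1,1,3
WI,Weakly important,0.666666666666667,1,1.5,3.8
FI,Fairly important,1.5,2,2.5,5.29
I,Important,2.5,3,3.5,6.69
VI,Very important,3.5,4,4.5,8.04
AI,Absolutely important,4.5,5,5.5,9.35
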