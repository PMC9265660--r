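unit,year,x,y,weight
A,2000,2,4,4
B,2000,4,4,4
C,2000,5,5,5
D,2000,10,5,5
A,2001,2,4,4
B,2001,4,4,4
C,2001,5,5,5
D,2001,10,5,5
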