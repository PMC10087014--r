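clone,parent,t0,t50,t100
A,normal,60,70,90
B,A,20,45,60
C,B,0,10,40
D,normal,10,5,0
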