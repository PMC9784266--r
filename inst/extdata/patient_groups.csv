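,g,i,f,m,a,e
p1,1,0,1,1,1,1
p2,1,0,1,0,1,1
p3,0,1,0,0,0,0
p4,0,0,1,1,1,1
p5,1,1,1,0,1,1
p6,1,1,1,1,1,1
p7,1,0,0,1,0,1
p8,0,1,1,0,1,1
p9,0,0,0,0,1,1
p10,0,0,0,1,0,1
p11,0,1,0,1,0,1
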