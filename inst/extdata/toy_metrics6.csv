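aa,m1,m2
framework,graph,information
G,0,0
A,1,1
S,3,3
V,6,6
F,10,10
W,15,15
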