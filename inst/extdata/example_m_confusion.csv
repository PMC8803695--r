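stage,M0,M1a,M1b_u,M1b_o,M1b_d,M1c
M0,8,5,4,0,0,0
M1a,2,6,1,0,0,0
M1b_u,1,0,7,4,0,1
M1b_o,0,0,0,3,1,0
M1b_d,0,0,0,1,6,0
M1c,0,0,0,0,0,2
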