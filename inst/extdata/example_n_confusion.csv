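stage,N0,N1,N2
N0,14,7,1
N1,2,11,4
N2,0,3,10
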