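0,0,1,0,0,0
5,3,0,0,0,0
4,3,3,0,0,0
0,2,0,4,0,0
0,0,2,4,4,0
0,0,3,3,3,0
0,0,0,2,2,2
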