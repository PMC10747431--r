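dose,n,affected
0,10,0
37.5,10,3
75,10,3
150,10,4
300,10,4
600,10,5
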