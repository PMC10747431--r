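dose,n,affected
0,10,0
37.5,10,1
75,10,2
150,10,2
300,10,5
600,10,6
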