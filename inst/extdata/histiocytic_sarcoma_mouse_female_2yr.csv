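dose,n,affected
0,49,0
75,50,1
150,50,1
300,50,4
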