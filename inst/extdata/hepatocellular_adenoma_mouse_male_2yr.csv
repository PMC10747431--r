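dose,n,affected
0,50,24
75,50,35
150,50,37
300,50,33
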