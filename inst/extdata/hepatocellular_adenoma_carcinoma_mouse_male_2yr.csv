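dose,n,affected
0,50,28
75,50,43
150,50,43
300,50,43
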