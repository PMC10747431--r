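dose,n,affected
0,47,0
75,43,0
150,49,0
300,48,2
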