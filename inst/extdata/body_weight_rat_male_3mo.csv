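dose,n,mean,sd
0,10,352,8
37.5,10,325,3
75,10,334,6
150,10,336,7
300,10,326,6
600,10,307,7
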