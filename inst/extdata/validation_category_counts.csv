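stack,PS,NP,OS,US,FP,ND
1,97,48,8,1,18,7
2,61,31,10,0,6,4
3,47,21,5,1,11,2
4,57,34,3,4,6,3
5,59,35,14,6,9,4
6,36,20,23,1,2,12
7,13,27,1,0,2,59
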