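stack,quality,TP,FP,FN,recall,precision,f_measure,accuracy
1,II,145,27,7,0.95,0.84,0.9,0.81
1,I,97,75,7,0.93,0.56,0.7,0.54
2,II,92,16,4,0.96,0.85,0.9,0.82
2,I,61,47,4,0.94,0.56,0.71,0.54
3,II,68,17,2,0.97,0.8,0.88,0.78
3,I,47,38,2,0.96,0.55,0.7,0.54
4,II,91,13,3,0.97,0.88,0.92,0.85
4,I,57,47,3,0.95,0.55,0.7,0.53
5,II,94,29,4,0.96,0.76,0.85,0.74
5,I,59,64,4,0.94,0.48,0.63,0.46
6,II,56,26,12,0.82,0.68,0.75,0.6
6,I,36,46,12,0.75,0.44,0.55,0.38
7,II,40,3,59,0.40,0.93,0.56,0.39
7,I,13,30,59,0.18,0.3,0.23,0.13
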