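image,ground_truth,predicted,tp,fp,fn,precision,accuracy,f1
1,10,9,9,0,0,1.00,1.00,1.00
2,8,7,7,0,0,1.00,1.00,1.00
3,10,9,8,0,0,1.00,1.00,1.00
4,11,10,10,0,1,1.00,0.91,0.95
5,10,10,10,0,0,1.00,1.00,1.00
6,9,9,8,1,0,0.89,0.89,0.94
7,10,9,9,0,0,1.00,1.00,1.00
8,6,6,6,0,0,1.00,1.00,1.00
9,12,11,10,0,1,1.00,0.91,0.95
10,12,12,11,0,1,1.00,0.92,0.96
11,13,12,10,0,1,1.00,0.91,0.95
12,11,10,9,0,1,1.00,0.90,0.95
13,6,6,6,0,0,1.00,1.00,1.00
14,8,8,8,0,0,1.00,1.00,1.00
15,16,15,13,2,1,0.87,0.81,0.90
16,2,2,2,0,0,1.00,1.00,1.00
17,10,10,10,0,0,1.00,1.00,1.00
18,1,1,1,0,0,1.00,1.00,1.00
19,11,10,10,0,0,1.00,1.00,1.00
20,7,7,7,0,0,1.00,1.00,1.00
21,8,7,7,0,1,1.00,0.88,0.93
22,8,7,7,0,1,1.00,0.88,0.93
23,10,10,10,0,0,1.00,1.00,1.00
24,11,10,10,0,1,1.00,0.91,0.95
25,2,2,2,0,0,1.00,1.00,1.00
26,8,8,7,0,0,1.00,1.00,1.00
27,9,8,7,0,1,1.00,0.88,0.93
28,12,10,10,0,2,1.00,0.83,0.91
29,7,7,7,0,0,1.00,1.00,1.00
30,8,8,7,1,0,0.88,0.88,0.93
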