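mtf,p_dow,p_rtd,r_out
1,0.25,0.05,10
2,0.25,0.05,10
3,0.25,0.05,10
4,0.25,0.05,10
5,0.25,0.05,10
6,0.15,0.10,20
7,0.15,0.10,20
8,0.15,0.10,20
9,0.15,0.10,20
10,0.15,0.10,20
11,0.10,0.15,20
12,0.10,0.15,20
13,0.10,0.15,20
14,0.10,0.15,20
15,0.10,0.15,20
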