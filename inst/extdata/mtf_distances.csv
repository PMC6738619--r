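mtf,source_1,source_2,source_3,source_4,source_5
1,25,41,44,37,39
2,31,26,28,49,32
3,38,41,34,31,36
4,44,42,33,30,47
5,43,30,28,29,35
6,45,49,37,33,34
7,39,49,42,33,28
8,39,38,49,25,46
9,47,48,41,42,48
10,31,31,27,39,30
11,30,35,43,28,47
12,29,38,48,29,46
13,27,26,43,46,33
14,26,28,33,43,34
15,27,38,44,30,25
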