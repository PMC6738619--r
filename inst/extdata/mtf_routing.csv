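mtf,source_1,source_2,source_3,source_4,source_5
1,0.0064,0.0219,0.0589,0.1063,0.1054
2,0.1144,0.0916,0.1019,0.1062,0.0653
3,0.0760,0.0772,0.0273,0.1163,0.0126
4,0.0798,0.0609,0.0876,0.0912,0.0552
5,0.0177,0.1052,0.0084,0.0076,0.0148
6,0.0255,0.0460,0.1242,0.1078,0.0361
7,0.0335,0.0335,0.0722,0.0049,0.0563
8,0.1150,0.0962,0.0620,0.0351,0.1146
9,0.0638,0.0576,0.0937,0.0436,0.0289
10,0.1119,0.1092,0.0825,0.0218,0.0808
11,0.0359,0.0703,0.0598,0.0305,0.1011
12,0.0877,0.1057,0.1010,0.0265,0.0459
13,0.0964,0.0635,0.0781,0.0868,0.0453
14,0.0256,0.0449,0.0048,0.1038,0.1372
15,0.1105,0.0163,0.0376,0.1116,0.1006
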