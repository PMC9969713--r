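plant,stage,h_m,w_m,l_m,v_m,h_c,w_c,l_c,v_c
1,sprout,102,176,101,1813.15,93,175,124,2018.1
2,sprout,134,103,115,1587.23,137,108,110,1627.56
3,sprout,157,129,115,2329.1,153,126,113,2178.41
4,sprout,159,80,92,1170.24,160,82,98,1285.76
5,sprout,148,179,120,3179.04,149,182,110,2982.98
6,sprout,159,167,210,5576.13,152,167,212,5381.41
7,sprout,135,126,117,1990.17,138,136,124,2327.23
8,sprout,110,118,141,1830.18,105,118,128,1585.92
9,sprout,155,190,141,4152.45,151,171,157,4053.9
10,sprout,90,215,135,2612.25,88,214,176,3314.43
11,sprout,124,232,181,5207.01,116,273,164,5193.55
12,sprout,126,137,156,2692.87,133,139,161,2976.41
13,sprout,158,219,162,5605.52,150,213,157,5016.15
14,sprout,65,147,138,1318.59,69,144,103,1023.41
15,sprout,134,150,144,2894.4,129,126,177,2876.96
16,sprout,123,214,183,4816.93,112,209,171,4002.77
17,sprout,165,196,139,4495.26,156,202,147,4632.26
18,sprout,124,168,146,3041.47,128,148,131,2481.66
19,sprout,125,146,158,2883.5,121,139,143,2405.12
20,sprout,162,295,156,7455.24,168,282,129,6111.5
1,seedling,96,144,201,2778.62,99,138,214,2923.67
2,seedling,274,220,148,8921.44,273,200,158,8626.8
3,seedling,263,202,176,9350.18,271,175,179,8489.08
4,seedling,232,203,223,10502.41,236,206,201,9771.82
5,seedling,299,264,215,16971.24,292,250,202,14746
6,seedling,274,222,176,10705.73,268,210,144,8104.32
7,seedling,166,212,227,7988.58,173,210,239,8682.87
8,seedling,249,207,163,8401.51,246,216,173,9192.53
9,seedling,338,213,292,21022.25,334,234,291,22743.4
10,seedling,201,166,248,8274.77,195,160,223,6957.6
11,seedling,258,259,288,19244.74,254,251,273,17404.84
12,seedling,266,192,300,15321.6,269,204,241,13225.12
13,seedling,263,288,301,22798.94,261,300,267,20906.1
14,seedling,156,151,242,5700.55,160,146,229,5349.44
15,seedling,262,224,178,10446.46,257,235,202,12199.79
16,seedling,225,212,215,10255.5,221,218,185,8912.93
17,seedling,259,202,205,10725.19,256,172,196,8630.27
18,seedling,283,222,199,12502.37,276,224,229,14157.7
19,seedling,281,201,172,9714.73,283,215,154,9370.13
20,seedling,270,226,321,19587.42,263,231,303,18408.16
1,flowering,156,151,244,5747.66,159,146,234,5432.08
2,flowering,273,309,299,25222.74,273,321,247,21645.35
3,flowering,210,225,281,13277.25,219,222,202,9820.84
4,flowering,297,344,223,22783.46,292,348,232,23574.91
5,flowering,281,370,219,22769.43,285,357,236,24011.82
6,flowering,319,231,231,17022.16,315,239,212,15960.42
7,flowering,268,229,324,19884.53,266,224,287,17100.61
8,flowering,270,303,220,17998.2,276,338,210,19590.48
9,flowering,361,306,406,44849.2,360,311,359,40193.64
10,flowering,247,222,331,18150.05,240,238,289,16507.68
11,flowering,331,209,349,24143.47,326,217,303,21434.83
12,flowering,299,230,227,15610.79,292,238,205,14246.68
13,flowering,311,386,296,35533.62,314,398,278,34742.22
14,flowering,204,331,217,14652.71,195,343,220,14714.7
15,flowering,336,293,193,19000.46,336,310,188,19582.08
16,flowering,315,330,324,33679.8,304,343,325,33888.4
17,flowering,252,296,246,18349.63,257,281,219,15815.52
18,flowering,337,224,296,22344.45,330,231,292,22259.16
19,flowering,314,223,164,11483.61,309,227,174,12204.88
20,flowering,321,232,395,29416.44,325,240,368,28704
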