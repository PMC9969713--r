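group,time_icp_s,time_psc_s,acc_icp,acc_psc
1,5.74,2.099,90.54,94.54
2,5.953,2.157,89.87,91.89
3,4.889,2.136,90.54,92.57
4,5.2,2.081,95.27,94.22
5,5.434,2.042,92.57,92.64
6,5.157,2.198,95.62,91.92
7,4.618,2.032,96.62,92.53
8,5.618,2.129,96.92,92.87
9,5.635,2.355,97.97,93.58
10,5.579,2.069,98.65,94.58
11,5.604,2.278,97.97,92.64
12,5.716,2.088,95.32,95.6
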