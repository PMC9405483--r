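rat,timepoint_h,plasma_ng_ml,brain_ng_g
1,1,259.93,1058.50
2,1,6326.57,16886.61
3,1,800.39,1475.58
4,1,198.69,642.07
5,1,2295.02,2455.34
6,24,23.20,111.08
7,24,26.20,79.98
8,24,28.67,105.28
9,24,22.50,NA
10,24,20.40,69.35
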