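structure,metric,variant,mean,sd
PTV,V95,AAA1,99.03,0.43
PTV,V95,AAA3,97.81,0.42
PTV,V95,AAA5,91.28,1.15
PTV,V95,AXB1,96.65,0.73
PTV,V95,AXB2,96.60,0.72
PTV,V95,AXB3,96.94,0.71
PTV,D_median,AAA1,80.25,0.20
PTV,D_median,AAA3,80.16,0.20
PTV,D_median,AAA5,79.66,0.27
PTV,D_median,AXB1,79.54,0.19
PTV,D_median,AXB2,79.53,0.18
PTV,D_median,AXB3,80.20,0.24
PTV,D_mean,AAA1,79.85,0.18
PTV,D_mean,AAA3,79.51,0.18
PTV,D_mean,AAA5,78.60,0.23
PTV,D_mean,AXB1,79.10,0.20
PTV,D_mean,AXB2,79.01,0.18
PTV,D_mean,AXB3,79.53,0.22
PTV,D_max,AAA1,84.42,0.70
PTV,D_max,AAA3,83.30,0.39
PTV,D_max,AAA5,82.70,0.53
PTV,D_max,AXB1,84.98,0.76
PTV,D_max,AXB2,84.24,0.73
PTV,D_max,AXB3,84.45,0.77
PTV,D_min,AAA1,64.99,5.13
PTV,D_min,AAA3,64.65,4.77
PTV,D_min,AAA5,61.17,3.87
PTV,D_min,AXB1,58.34,4.95
PTV,D_min,AXB2,59.48,4.69
PTV,D_min,AXB3,61.75,4.84
PTV,CI,AAA1,1.09,0.02
PTV,CI,AAA3,1.04,0.02
PTV,CI,AAA5,0.93,0.02
PTV,CI,AXB1,1.04,0.02
PTV,CI,AXB2,1.03,0.02
PTV,CI,AXB3,1.03,0.02
PTV,CN,AAA1,0.90,0.01
PTV,CN,AAA3,0.92,0.01
PTV,CN,AAA5,0.90,0.01
PTV,CN,AXB1,0.90,0.01
PTV,CN,AXB2,0.91,0.01
PTV,CN,AXB3,0.92,0.01
PTV,HI,AAA1,0.09,0.01
PTV,HI,AAA3,0.10,0.00
PTV,HI,AAA5,0.14,0.01
PTV,HI,AXB1,0.12,0.01
PTV,HI,AXB2,0.11,0.01
PTV,HI,AXB3,0.11,0.01
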