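structure,metric,variant,mean,sd
PTV,TCP,AAA1,87.49,2.02
PTV,TCP,AAA3,86.59,2.14
PTV,TCP,AAA5,82.37,3.07
PTV,TCP,AXB1,83.44,3.06
PTV,TCP,AXB2,84.32,2.44
PTV,TCP,AXB3,85.69,2.23
Bladder,NTCP,AAA1,0.05,0.18
Bladder,NTCP,AAA3,0.05,0.19
Bladder,NTCP,AAA5,0.04,0.15
Bladder,NTCP,AXB1,0.05,0.18
Bladder,NTCP,AXB2,0.05,0.18
Bladder,NTCP,AXB3,0.05,0.19
Rectum,NTCP,AAA1,6.11,3.18
Rectum,NTCP,AAA3,5.55,2.79
Rectum,NTCP,AAA5,4.77,2.52
Rectum,NTCP,AXB1,3.23,1.58
Rectum,NTCP,AXB2,3.42,1.66
Rectum,NTCP,AXB3,3.99,1.93
FemoralHead_R,NTCP,AAA1,0.04,0.11
FemoralHead_R,NTCP,AAA3,0.04,0.11
FemoralHead_R,NTCP,AAA5,0.04,0.10
FemoralHead_R,NTCP,AXB1,0.03,0.08
FemoralHead_R,NTCP,AXB2,0.03,0.09
FemoralHead_R,NTCP,AXB3,0.03,0.09
FemoralHead_L,NTCP,AAA1,0.05,0.14
FemoralHead_L,NTCP,AAA3,0.05,0.13
FemoralHead_L,NTCP,AAA5,0.04,0.12
FemoralHead_L,NTCP,AXB1,0.03,0.10
FemoralHead_L,NTCP,AXB2,0.03,0.10
FemoralHead_L,NTCP,AXB3,0.04,0.11
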