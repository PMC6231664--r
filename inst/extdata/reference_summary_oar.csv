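structure,metric,variant,mean
Bladder,D_max_pct,AAA1,107.33
Bladder,D_min_pct,AAA1,1.40
Bladder,D_mean_pct,AAA1,27.97
Bladder,D_median_pct,AAA1,14.27
Bladder,D_max_pct,AAA3,106.19
Bladder,D_min_pct,AAA3,1.44
Bladder,D_mean_pct,AAA3,28.18
Bladder,D_median_pct,AAA3,14.83
Bladder,D_max_pct,AAA5,105.18
Bladder,D_min_pct,AAA5,1.47
Bladder,D_mean_pct,AAA5,28.27
Bladder,D_median_pct,AAA5,15.53
Bladder,D_max_pct,AXB1,107.19
Bladder,D_min_pct,AXB1,1.34
Bladder,D_mean_pct,AXB1,27.49
Bladder,D_median_pct,AXB1,13.73
Bladder,D_max_pct,AXB2,106.55
Bladder,D_min_pct,AXB2,1.34
Bladder,D_mean_pct,AXB2,27.48
Bladder,D_median_pct,AXB2,13.80
Bladder,D_max_pct,AXB3,106.70
Bladder,D_min_pct,AXB3,1.36
Bladder,D_mean_pct,AXB3,27.79
Bladder,D_median_pct,AXB3,14.18
Rectum,D_max_pct,AAA1,104.54
Rectum,D_min_pct,AAA1,2.33
Rectum,D_mean_pct,AAA1,51.69
Rectum,D_median_pct,AAA1,49.14
Rectum,D_max_pct,AAA3,103.71
Rectum,D_min_pct,AAA3,2.38
Rectum,D_mean_pct,AAA3,51.50
Rectum,D_median_pct,AAA3,48.94
Rectum,D_max_pct,AAA5,103.01
Rectum,D_min_pct,AAA5,2.42
Rectum,D_mean_pct,AAA5,50.91
Rectum,D_median_pct,AAA5,48.37
Rectum,D_max_pct,AXB1,105.16
Rectum,D_min_pct,AXB1,2.21
Rectum,D_mean_pct,AXB1,48.82
Rectum,D_median_pct,AXB1,47.07
Rectum,D_max_pct,AXB2,104.41
Rectum,D_min_pct,AXB2,2.21
Rectum,D_mean_pct,AXB2,49.02
Rectum,D_median_pct,AXB2,47.14
Rectum,D_max_pct,AXB3,104.81
Rectum,D_min_pct,AXB3,2.26
Rectum,D_mean_pct,AXB3,49.59
Rectum,D_median_pct,AXB3,47.52
FemoralHead_R,D_max_pct,AAA1,47.71
FemoralHead_R,D_min_pct,AAA1,5.63
FemoralHead_R,D_mean_pct,AAA1,27.83
FemoralHead_R,D_median_pct,AAA1,28.58
FemoralHead_R,D_max_pct,AAA3,47.54
FemoralHead_R,D_min_pct,AAA3,5.93
FemoralHead_R,D_mean_pct,AAA3,27.87
FemoralHead_R,D_median_pct,AAA3,28.56
FemoralHead_R,D_max_pct,AAA5,47.21
FemoralHead_R,D_min_pct,AAA5,6.33
FemoralHead_R,D_mean_pct,AAA5,27.76
FemoralHead_R,D_median_pct,AAA5,28.39
FemoralHead_R,D_max_pct,AXB1,47.11
FemoralHead_R,D_min_pct,AXB1,5.27
FemoralHead_R,D_mean_pct,AXB1,27.25
FemoralHead_R,D_median_pct,AXB1,28.00
FemoralHead_R,D_max_pct,AXB2,47.11
FemoralHead_R,D_min_pct,AXB2,5.36
FemoralHead_R,D_mean_pct,AXB2,27.25
FemoralHead_R,D_median_pct,AXB2,27.99
FemoralHead_R,D_max_pct,AXB3,47.23
FemoralHead_R,D_min_pct,AXB3,5.58
FemoralHead_R,D_mean_pct,AXB3,27.46
FemoralHead_R,D_median_pct,AXB3,28.19
FemoralHead_L,D_max_pct,AAA1,47.17
FemoralHead_L,D_min_pct,AAA1,4.90
FemoralHead_L,D_mean_pct,AAA1,26.30
FemoralHead_L,D_median_pct,AAA1,27.25
FemoralHead_L,D_max_pct,AAA3,46.88
FemoralHead_L,D_min_pct,AAA3,5.09
FemoralHead_L,D_mean_pct,AAA3,26.36
FemoralHead_L,D_median_pct,AAA3,27.26
FemoralHead_L,D_max_pct,AAA5,46.59
FemoralHead_L,D_min_pct,AAA5,5.33
FemoralHead_L,D_mean_pct,AAA5,26.28
FemoralHead_L,D_median_pct,AAA5,27.06
FemoralHead_L,D_max_pct,AXB1,46.48
FemoralHead_L,D_min_pct,AXB1,4.64
FemoralHead_L,D_mean_pct,AXB1,25.74
FemoralHead_L,D_median_pct,AXB1,26.71
FemoralHead_L,D_max_pct,AXB2,46.44
FemoralHead_L,D_min_pct,AXB2,4.67
FemoralHead_L,D_mean_pct,AXB2,25.74
FemoralHead_L,D_median_pct,AXB2,26.71
FemoralHead_L,D_max_pct,AXB3,46.42
FemoralHead_L,D_min_pct,AXB3,4.81
FemoralHead_L,D_mean_pct,AXB3,25.95
FemoralHead_L,D_median_pct,AXB3,26.89
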