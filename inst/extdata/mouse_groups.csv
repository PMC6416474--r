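"group","fluence_rate_mW_cm2","time_s","fluence_J_cm2","bpd_uM","power_W","study_dose_mM","dose_1.00mm_mM","dose_0.50mm_mM","dose_0.25mm_mM","k_per_day","ci"
1,50,600,30,0.53,0.0393,0.39,0.4067,0.4057,0.4054,0.4,0.0377
2,75,400,30,0.72,0.0589,0.45,0.4607,0.4633,0.4638,0.38,0.0556
3,150,200,30,0.56,0.1178,0.29,0.2913,0.2936,0.2941,0.4,0.0237
4,50,1400,70,0.73,0.0393,0.9,0.9147,0.92,0.9213,0.28,0.3151
5,75,1333,100,0.41,0.0589,0.6,0.5977,0.6032,0.6044,0.37,0.1037
6,50,2700,135,0.5,0.0393,0.78,0.7839,0.791,0.7928,0.34,0.1646
7,75,1800,135,0.53,0.0589,0.82,0.8246,0.8319,0.8337,0.32,0.2139
8,150,900,135,0.58,0.1178,0.85,0.8626,0.8684,0.8698,0.28,0.324
9,75,2000,150,0.84,0.0589,1.3,1.3094,1.3196,1.3222,0,1
10,100,1500,150,0.66,0.0785,1.03,1.0292,1.0373,1.0393,0.11,0.7432
11,75,3333,250,0.58,0.0589,0.96,0.96,0.963,0.9637,0.25,0.3878
12,150,1667,250,0.77,0.1178,1.26,1.2599,1.2651,1.2664,0,1
13,150,2000,300,0.77,0.1178,1.27,1.2728,1.2758,1.2766,0,1
14,150,2333,350,0.81,0.1178,1.35,1.3432,1.345,1.3454,0,1
15,0,0,0,NA,NA,NA,NA,NA,NA,0.41,0
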