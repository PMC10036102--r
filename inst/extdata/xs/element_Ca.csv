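energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,669.446,667.541,667.539,0.196105,1.71055
5.27736,574.147,572.314,572.312,0.195899,1.63837
5.5701,492.433,490.672,490.67,0.195682,1.56682
5.87908,422.366,420.677,420.674,0.195454,1.49604
6.2052,362.285,360.666,360.664,0.195214,1.42618
6.54941,310.766,309.216,309.214,0.194961,1.3574
6.91271,266.588,265.106,265.104,0.194695,1.28985
7.29616,228.704,227.288,227.286,0.194416,1.2237
7.70089,196.216,194.866,194.863,0.194122,1.15909
8.12807,168.355,167.068,167.065,0.193813,1.09617
8.57894,144.461,143.236,143.233,0.193489,1.03506
9.05482,123.969,122.803,122.8,0.193147,0.975893
9.55711,106.394,105.286,105.282,0.192789,0.918755
10.0872,91.3194,90.2669,90.2633,0.192413,0.863733
10.6468,78.3898,77.3908,77.3869,0.192018,0.810891
11.2374,67.2993,66.3515,66.3474,0.191603,0.760274
11.8607,57.7858,56.887,56.8828,0.191168,0.711906
12.5187,49.6247,48.7727,48.7682,0.190712,0.665797
13.2131,42.6235,41.8159,41.8113,0.190233,0.621939
13.946,36.6168,35.8517,35.8468,0.189732,0.580309
14.7196,31.4632,30.7382,30.7331,0.189206,0.540871
15.5362,26.9677,26.2809,26.2755,0.188655,0.503579
16.398,23.0872,22.4364,22.4308,0.188079,0.468376
17.3076,19.7713,19.1545,19.1486,0.187475,0.435199
18.2677,16.9375,16.3529,16.3467,0.186843,0.403979
19.281,14.5156,13.9613,13.9548,0.186183,0.374641
20.3505,12.4302,11.9044,11.8976,0.185493,0.347109
21.4794,10.6225,10.1235,10.1164,0.184771,0.321305
22.6709,9.08306,8.60934,8.6019,0.184018,0.297148
23.9285,7.7719,7.32189,7.3141,0.183232,0.274561
25.2558,6.65498,6.22724,6.21911,0.182412,0.253464
26.6568,5.70338,5.29654,5.28804,0.181557,0.23378
28.1354,4.89247,4.50525,4.49637,0.180666,0.215435
29.6962,4.20131,3.83248,3.82322,0.179739,0.198356
31.3434,3.60288,3.2513,3.24163,0.178773,0.182472
33.0821,3.09219,2.75679,2.74671,0.17777,0.167714
34.9172,2.65809,2.33786,2.32735,0.176727,0.154018
36.8541,2.28898,1.98296,1.97201,0.175644,0.141321
38.8984,1.97501,1.68233,1.67093,0.17452,0.129563
41.0562,1.70626,1.42607,1.41422,0.173355,0.118686
43.3336,1.47628,1.20782,1.1955,0.172149,0.108634
45.7374,1.28086,1.02341,1.0106,0.1709,0.0993566
48.2745,1.11472,0.867601,0.854306,0.169608,0.0908024
50.9523,0.972897,0.735495,0.7217,0.168273,0.0829238
53.7787,0.851494,0.623225,0.608923,0.166896,0.0756754
56.7619,0.748258,0.528585,0.513769,0.165475,0.0690139
59.9105,0.660394,0.448822,0.433484,0.164011,0.0628983
63.2338,0.584738,0.380809,0.364943,0.162505,0.0572896
66.7415,0.520328,0.323619,0.307221,0.160956,0.0521512
70.4437,0.465442,0.275563,0.258628,0.159365,0.0474482
74.3513,0.418602,0.235195,0.217721,0.157733,0.0431479
78.4756,0.378565,0.2013,0.183285,0.156061,0.0392196
82.8288,0.343877,0.172451,0.153894,0.154349,0.0356344
87.4234,0.313993,0.148128,0.129029,0.152598,0.0323652
92.2729,0.28838,0.127821,0.108183,0.15081,0.0293869
97.3913,0.266366,0.110878,0.0907038,0.148987,0.0266759
102.794,0.246988,0.0963556,0.0756489,0.147129,0.0242102
108.496,0.229982,0.0840076,0.0627742,0.145238,0.0219695
114.514,0.215342,0.0738438,0.0520907,0.143316,0.0199349
120.866,0.20268,0.06549,0.0432254,0.141366,0.0180889
127.571,0.191672,0.0586356,0.0358689,0.139388,0.0164153
134.648,0.182048,0.0530225,0.0297644,0.137385,0.0148993
142.117,0.173585,0.0484365,0.0246988,0.135359,0.0135269
150,0.166094,0.0446996,0.0204953,0.133313,0.0122856
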