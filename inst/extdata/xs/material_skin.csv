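energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,38.5855,37.9239,37.9218,0.215738,0.447956
5.27736,32.7094,32.0711,32.069,0.215511,0.424966
5.5701,27.7382,27.1227,27.1204,0.215273,0.402519
5.87908,23.5319,22.9386,22.9362,0.215022,0.380664
6.2052,20.0122,19.4406,19.438,0.214757,0.359445
6.54941,17.0474,16.4967,16.494,0.214479,0.338901
6.91271,14.5293,13.9989,13.9961,0.214187,0.319065
7.29616,12.3903,11.8794,11.8765,0.21388,0.299965
7.70089,10.5731,10.0811,10.078,0.213556,0.281622
8.12807,9.02649,8.5525,8.54922,0.213217,0.264052
8.57894,7.70718,7.25051,7.24706,0.212859,0.247262
9.05482,6.58704,6.14692,6.1433,0.212484,0.231256
9.55711,5.63582,5.21151,5.2077,0.21209,0.216031
10.0872,4.82299,4.41375,4.40974,0.211676,0.201578
10.6468,4.11174,3.71682,3.71261,0.211242,0.187885
11.2374,3.51149,3.13019,3.12577,0.210786,0.174936
11.8607,3.00477,2.63639,2.63175,0.210307,0.162712
12.5187,2.57685,2.22074,2.21586,0.209805,0.151191
13.2131,2.21536,1.87086,1.86574,0.209278,0.140349
13.946,1.90986,1.57635,1.57098,0.208727,0.13016
14.7196,1.65156,1.32846,1.32282,0.208148,0.120598
15.5362,1.43007,1.11681,1.11089,0.207542,0.111635
16.398,1.24175,0.937799,0.931595,0.206908,0.103245
17.3076,1.0829,0.787762,0.781259,0.206244,0.0953995
18.2677,0.948823,0.662017,0.655202,0.205549,0.0880716
19.281,0.835557,0.556639,0.5495,0.204823,0.0812347
20.3505,0.738957,0.467506,0.460031,0.204063,0.0748627
21.4794,0.655879,0.391504,0.383679,0.20327,0.0689302
22.6709,0.585867,0.3282,0.320013,0.202441,0.0634128
23.9285,0.526786,0.275486,0.266923,0.201576,0.0582869
25.2558,0.476854,0.231602,0.222651,0.200674,0.0535296
26.6568,0.434582,0.195083,0.18573,0.199733,0.0491192
28.1354,0.398726,0.164707,0.154938,0.198753,0.0450348
29.6962,0.368246,0.139454,0.129257,0.197733,0.0412564
31.3434,0.341538,0.117741,0.107102,0.196671,0.0377648
33.0821,0.31872,0.0997052,0.0886108,0.195567,0.0345419
34.9172,0.29931,0.0848823,0.0733198,0.19442,0.0315701
36.8541,0.282735,0.0727169,0.0606735,0.193228,0.0288329
38.8984,0.26852,0.0627503,0.0502135,0.191992,0.0263146
41.0562,0.25607,0.0544017,0.0413595,0.190711,0.024
43.3336,0.245155,0.0474558,0.0338964,0.189383,0.0218749
45.7374,0.235721,0.0418739,0.0277862,0.188009,0.0199259
48.2745,0.227511,0.0374091,0.0227826,0.186588,0.0181402
50.9523,0.220223,0.0337732,0.0185979,0.18512,0.0165057
53.7787,0.213676,0.0307936,0.0150603,0.183604,0.015011
56.7619,0.207891,0.028504,0.0122043,0.182041,0.0136456
59.9105,0.202727,0.02677,0.00989656,0.180431,0.0123993
63.2338,0.197622,0.0250394,0.00758565,0.178774,0.0112628
66.7415,0.193305,0.0240468,0.0060072,0.17707,0.0102274
70.4437,0.18938,0.023405,0.00477515,0.17532,0.00928476
74.3513,0.185752,0.0230229,0.00379964,0.173525,0.00842743
78.4756,0.182359,0.0228445,0.00302585,0.171685,0.00764828
82.8288,0.179019,0.0226924,0.00227754,0.169801,0.00694076
87.4234,0.175875,0.0227116,0.00170114,0.167875,0.00629878
92.2729,0.172904,0.0228828,0.0012788,0.165909,0.00571674
97.3913,0.170058,0.02316,0.000965756,0.163902,0.00518945
102.794,0.167057,0.0232666,0.00048684,0.161858,0.00471212
108.496,0.164316,0.0236164,0.000257255,0.159778,0.00428035
114.514,0.161742,0.0241183,0.00018744,0.157664,0.00389009
120.866,0.159206,0.0246434,0.000149836,0.155518,0.00353762
127.571,0.156684,0.0251683,0.000122341,0.153342,0.00321953
134.648,0.154172,0.025687,0.000100385,0.151139,0.00293269
142.117,0.151667,0.0261967,8.24804e-05,0.14891,0.00267425
150,0.149169,0.0266954,6.7802e-05,0.146659,0.00244159
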