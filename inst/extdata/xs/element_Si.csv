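energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,239.448,238.168,238.166,0.195886,1.08549
5.27736,205.413,204.184,204.182,0.19568,1.03612
5.5701,176.229,175.048,175.046,0.195463,0.987418
5.87908,151.203,150.07,150.068,0.195235,0.939492
6.2052,129.548,128.463,128.461,0.194995,0.892452
6.54941,110.906,109.867,109.865,0.194743,0.846407
6.91271,94.9565,93.9631,93.9606,0.194478,0.801462
7.29616,81.3106,80.3613,80.3587,0.194198,0.757716
7.70089,69.6349,68.7286,68.7258,0.193905,0.715257
8.12807,59.6014,58.7366,58.7337,0.193596,0.674166
8.57894,50.9335,50.1088,50.1057,0.193272,0.634509
9.05482,43.5345,42.7485,42.7452,0.192932,0.596342
9.55711,37.2182,36.4694,36.4659,0.192574,0.559706
10.0872,31.8115,31.0983,31.0947,0.192198,0.52463
10.6468,27.1337,26.4546,26.4508,0.191803,0.49113
11.2374,23.151,22.5044,22.5004,0.191389,0.459209
11.8607,19.7598,19.1442,19.14,0.190955,0.428859
12.5187,16.872,16.2859,16.2815,0.190499,0.400063
13.2131,14.4127,13.8545,13.8499,0.190021,0.372794
13.946,12.3179,11.7863,11.7814,0.18952,0.347017
14.7196,10.5336,10.027,10.0219,0.188994,0.322693
15.5362,8.99267,8.50982,8.50445,0.188444,0.299776
16.398,7.67346,7.21301,7.20738,0.187868,0.278216
17.3076,6.55335,6.11403,6.10813,0.187265,0.257963
18.2677,5.60213,5.18272,5.17653,0.186635,0.238961
19.281,4.79415,4.3935,4.38702,0.185975,0.221155
20.3505,4.10353,3.72055,3.71376,0.185285,0.204491
21.4794,3.50988,3.14351,3.1364,0.184565,0.188912
22.6709,3.00698,2.65624,2.6488,0.183812,0.174365
23.9285,2.58083,2.24478,2.23701,0.183027,0.160796
25.2558,2.21959,1.89736,1.88924,0.182208,0.148151
26.6568,1.91326,1.60402,1.59553,0.181354,0.136382
28.1354,1.65338,1.35635,1.34748,0.180464,0.125439
29.6962,1.43281,1.14725,1.138,0.179538,0.115274
31.3434,1.24278,0.96802,0.95836,0.178574,0.105842
33.0821,1.08122,0.816622,0.806549,0.177571,0.0971001
34.9172,0.944322,0.689285,0.678786,0.176529,0.0890062
36.8541,0.82823,0.582197,0.571262,0.175448,0.0815204
38.8984,0.7297,0.492153,0.48077,0.174325,0.0746047
41.0562,0.645385,0.415843,0.404001,0.173162,0.0682227
43.3336,0.573236,0.351252,0.33894,0.171956,0.0623396
45.7374,0.511988,0.297148,0.284357,0.170709,0.0569223
48.2745,0.459922,0.251844,0.238564,0.169418,0.0519395
50.9523,0.415407,0.21374,0.199961,0.168085,0.0473611
53.7787,0.377185,0.181602,0.167317,0.166709,0.0431588
56.7619,0.344598,0.154802,0.140002,0.16529,0.0393056
59.9105,0.316751,0.132467,0.117146,0.163828,0.0357762
63.2338,0.292527,0.113505,0.0976574,0.162323,0.0325466
66.7415,0.271772,0.0977816,0.081402,0.160776,0.029594
70.4437,0.253937,0.0847679,0.0678524,0.159187,0.0268974
74.3513,0.238552,0.0740125,0.0565581,0.157557,0.0244367
78.4756,0.225223,0.0651388,0.0471439,0.155886,0.0221934
82.8288,0.213455,0.0576648,0.0391285,0.154176,0.0201499
87.4234,0.203117,0.051476,0.032399,0.152428,0.0182902
92.2729,0.194068,0.0464428,0.0268268,0.150642,0.0165991
97.3913,0.186096,0.0423649,0.0222129,0.14882,0.0150626
102.794,0.178858,0.0389101,0.0182265,0.146964,0.0136676
108.496,0.172304,0.0360355,0.0148259,0.145076,0.0124021
114.514,0.166471,0.0337885,0.0120597,0.143156,0.011255
120.866,0.161233,0.0320494,0.00980966,0.141208,0.010216
127.571,0.156487,0.0307207,0.00797942,0.139232,0.0092756
134.648,0.152147,0.0297228,0.00649065,0.137231,0.00842516
142.117,0.148144,0.0289909,0.00527965,0.135208,0.00765662
150,0.144421,0.0284719,0.00429459,0.133164,0.00696263
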