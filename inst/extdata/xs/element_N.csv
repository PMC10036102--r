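energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,30.3,29.6646,29.6627,0.196389,0.440864
5.27736,25.6981,25.0859,25.084,0.196183,0.417932
5.5701,21.8035,21.214,21.212,0.195966,0.395565
5.87908,18.5072,17.9398,17.9376,0.195737,0.373812
6.2052,15.725,15.1791,15.1768,0.195497,0.352716
6.54941,13.3726,12.8475,12.8451,0.195244,0.332315
6.91271,11.3792,10.8741,10.8715,0.194977,0.312642
7.29616,9.68965,9.20393,9.20123,0.194698,0.293723
7.70089,8.25753,7.79039,7.78755,0.194403,0.275575
8.12807,7.04518,6.59585,6.59287,0.194094,0.258213
8.57894,6.02053,5.58825,5.58512,0.193769,0.241641
9.05482,5.15069,4.7347,4.7314,0.193427,0.22586
9.55711,4.41211,4.01165,4.00818,0.193069,0.210865
10.0872,3.77954,3.39384,3.3902,0.192692,0.196646
10.6468,3.21967,2.84801,2.84418,0.192296,0.183187
11.2374,2.74846,2.39013,2.38611,0.191881,0.170472
11.8607,2.35173,2.00604,2.00181,0.191445,0.158478
12.5187,2.01757,1.68384,1.6794,0.190988,0.147183
13.2131,1.73599,1.41358,1.40892,0.190509,0.136561
13.946,1.4986,1.1869,1.18201,0.190007,0.126587
14.7196,1.29835,0.996769,0.991635,0.18948,0.117232
15.5362,1.12692,0.834912,0.829526,0.188929,0.108469
16.398,0.981465,0.69849,0.692843,0.188351,0.10027
17.3076,0.859037,0.584601,0.578682,0.187747,0.0926084
18.2677,0.755901,0.489534,0.483331,0.187114,0.0854558
19.281,0.66893,0.41019,0.403691,0.186453,0.078786
20.3505,0.594732,0.343202,0.336397,0.185761,0.0725729
21.4794,0.530793,0.286085,0.278962,0.185039,0.0667913
22.6709,0.477035,0.238786,0.231333,0.184285,0.061417
23.9285,0.43176,0.199631,0.191836,0.183497,0.0564266
25.2558,0.393557,0.167231,0.159083,0.182676,0.0517975
26.6568,0.36125,0.140436,0.131922,0.18182,0.0475082
28.1354,0.333864,0.11829,0.109398,0.180928,0.043538
29.6962,0.310586,0.100002,0.0907198,0.179999,0.0398674
31.3434,0.290064,0.0842392,0.0745542,0.179033,0.0364772
33.0821,0.272518,0.0712401,0.0611407,0.178027,0.0333497
34.9172,0.257591,0.0606661,0.0501405,0.176983,0.0304675
36.8541,0.244832,0.0520828,0.0411195,0.175899,0.0278144
38.8984,0.23387,0.0451339,0.0337214,0.174773,0.0253748
41.0562,0.224192,0.0393242,0.0274516,0.173607,0.0231338
43.3336,0.215648,0.0345153,0.022172,0.172398,0.0210775
45.7374,0.208248,0.030732,0.0179078,0.171147,0.0191927
48.2745,0.201784,0.0277785,0.0144637,0.169854,0.0174666
50.9523,0.19598,0.0253895,0.0115752,0.168517,0.0158876
53.7787,0.190689,0.0234288,0.00910656,0.167138,0.0144445
56.7619,0.186006,0.0220022,0.0071644,0.165715,0.0131267
59.9105,0.18181,0.0209966,0.00563645,0.164249,0.0119246
63.2338,0.177745,0.0200638,0.00417543,0.16274,0.010829
66.7415,0.174108,0.0195095,0.00308783,0.161189,0.00983118
70.4437,0.170803,0.0192425,0.00228353,0.159596,0.00892331
74.3513,0.167749,0.0191879,0.00168873,0.157962,0.00809793
78.4756,0.164884,0.0192901,0.00124885,0.156287,0.00734816
82.8288,0.161368,0.0187121,0.000128148,0.154572,0.00666762
87.4234,0.158874,0.0191305,4.40578e-06,0.152819,0.00605039
92.2729,0.15652,0.0196666,1.51472e-07,0.151029,0.00549102
97.3913,0.154187,0.0202038,5.20768e-09,0.149203,0.00498448
102.794,0.151868,0.0207367,1e-09,0.147342,0.00452612
108.496,0.14956,0.0212641,1e-09,0.145449,0.00411168
114.514,0.147261,0.0217846,1e-09,0.143524,0.00373723
120.866,0.14497,0.0222969,1e-09,0.14157,0.00339918
127.571,0.142684,0.0227997,1e-09,0.13959,0.00309423
134.648,0.140403,0.0232919,1e-09,0.137584,0.00281935
142.117,0.138127,0.0237722,1e-09,0.135555,0.0025718
150,0.135855,0.0242394,1e-09,0.133506,0.00234904
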