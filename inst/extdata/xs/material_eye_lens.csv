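energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,37.7346,37.0738,37.0717,0.214994,0.447914
5.27736,31.9784,31.3409,31.3387,0.214768,0.424904
5.5701,27.1101,26.4954,26.4931,0.214531,0.40244
5.87908,22.9922,22.3998,22.3974,0.21428,0.38057
6.2052,19.548,18.9772,18.9747,0.214017,0.359337
6.54941,16.6479,16.098,16.0953,0.21374,0.338781
6.91271,14.1854,13.6558,13.653,0.213449,0.318935
7.29616,12.0943,11.5843,11.5813,0.213142,0.299827
7.70089,10.3183,9.82713,9.82403,0.21282,0.281479
8.12807,8.80733,8.33421,8.33095,0.212482,0.263904
8.57894,7.519,7.0632,7.05977,0.212126,0.247111
9.05482,6.42544,5.9862,5.98259,0.211752,0.231104
9.55711,5.49704,5.0736,5.0698,0.211359,0.215878
10.0872,4.70376,4.29537,4.29138,0.210947,0.201426
10.6468,4.00912,3.61507,3.61087,0.210514,0.187735
11.2374,3.42317,3.04273,3.03832,0.210059,0.174789
11.8607,2.92874,2.56122,2.55659,0.209582,0.162569
12.5187,2.51141,2.15613,2.15127,0.209082,0.151052
13.2131,2.15901,1.81535,1.81024,0.208557,0.140214
13.946,1.86133,1.52865,1.5233,0.208007,0.13003
14.7196,1.60976,1.28747,1.28185,0.207431,0.120473
15.5362,1.39414,1.08169,1.0758,0.206827,0.111515
16.398,1.21091,0.907762,0.90158,0.206195,0.10313
17.3076,1.05641,0.762069,0.755588,0.205533,0.09529
18.2677,0.926056,0.640039,0.633248,0.204841,0.0879673
19.281,0.815979,0.53784,0.530726,0.204117,0.0811356
20.3505,0.722124,0.451446,0.443996,0.20336,0.0747687
21.4794,0.641426,0.377814,0.370016,0.202569,0.0688412
22.6709,0.573444,0.316531,0.308373,0.201743,0.0633286
23.9285,0.516095,0.26554,0.257007,0.200881,0.0582074
25.2558,0.46764,0.223124,0.214204,0.199982,0.0534547
26.6568,0.426628,0.187856,0.178535,0.199045,0.0490487
28.1354,0.391847,0.158545,0.14881,0.198068,0.0449686
29.6962,0.362284,0.1342,0.124038,0.197051,0.0411942
31.3434,0.336367,0.11327,0.102667,0.195993,0.0377066
33.0821,0.314226,0.0959019,0.0848458,0.194893,0.0344873
34.9172,0.295392,0.0816459,0.0701232,0.19375,0.0315192
36.8541,0.279308,0.0699617,0.0579598,0.192562,0.0287854
38.8984,0.265511,0.0604034,0.0479098,0.191331,0.0262703
41.0562,0.253418,0.0524028,0.0394055,0.190053,0.0239588
43.3336,0.242808,0.045753,0.0322403,0.18873,0.0218367
45.7374,0.233634,0.040422,0.0263829,0.187361,0.0198905
48.2745,0.225646,0.0361697,0.0215935,0.185945,0.0181074
50.9523,0.218548,0.0327138,0.0175908,0.184482,0.0164754
53.7787,0.212162,0.0298869,0.0142079,0.182971,0.0149831
56.7619,0.206516,0.0277262,0.0114828,0.181414,0.0136198
59.9105,0.201471,0.0261012,0.00928588,0.179809,0.0123756
63.2338,0.196476,0.0244714,0.00707776,0.178158,0.011241
66.7415,0.192243,0.0235531,0.00557565,0.17646,0.0102073
70.4437,0.18839,0.022974,0.00440843,0.174716,0.00926639
74.3513,0.184826,0.0226455,0.00348847,0.172926,0.00841061
78.4756,0.181488,0.0225126,0.00276219,0.171093,0.00763289
82.8288,0.178186,0.0223878,0.0020433,0.169216,0.0069267
87.4234,0.175087,0.0224421,0.00150409,0.167297,0.00628596
92.2729,0.172156,0.0226438,0.00111427,0.165337,0.00570506
97.3913,0.169345,0.0229462,0.000828439,0.163338,0.00517882
102.794,0.166377,0.0230749,0.000373694,0.161301,0.00470245
108.496,0.163664,0.0234435,0.00016494,0.159228,0.00427157
114.514,0.161115,0.0239602,0.000111788,0.157121,0.00388213
120.866,0.1586,0.0244968,8.76391e-05,0.154982,0.00353041
127.571,0.156098,0.0250308,7.11053e-05,0.152814,0.00321301
134.648,0.153603,0.0255566,5.81297e-05,0.150618,0.0029268
142.117,0.151114,0.0260719,4.76088e-05,0.148397,0.00266893
150,0.14863,0.0265748,3.90131e-05,0.146154,0.0024368
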