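energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,153.323,152.309,152.307,0.197564,0.818099
5.27736,131.267,130.292,130.29,0.197357,0.779829
5.5701,112.398,111.461,111.459,0.197138,0.742179
5.87908,96.2531,95.3532,95.351,0.196908,0.705232
6.2052,82.3806,81.5172,81.5149,0.196666,0.669069
6.54941,70.4875,69.6598,69.6574,0.196412,0.633769
6.91271,60.321,59.528,59.5254,0.196144,0.599404
7.10844,55.656,54.8807,54.878,0.195998,0.581916
7.11556,60.5098,59.7352,59.7325,0.195993,0.581299
7.29616,56.3412,55.582,55.5793,0.195862,0.566044
7.70089,48.3193,47.5929,47.59,0.195566,0.533746
8.12807,41.4265,40.7317,40.7287,0.195255,0.502562
8.57894,35.4793,34.815,34.8118,0.194928,0.472535
9.05482,30.394,29.7591,29.7558,0.194585,0.443696
9.55711,26.0453,25.4385,25.435,0.194224,0.416068
10.0872,22.3151,21.7353,21.7316,0.193845,0.389664
10.6468,19.0772,18.5231,18.5192,0.193447,0.364488
11.2374,16.3161,15.7866,15.7825,0.193029,0.340535
11.8607,13.9613,13.4552,13.4509,0.192591,0.317793
12.5187,11.9527,11.4688,11.4643,0.192131,0.296243
13.2131,10.2391,9.77633,9.77164,0.191649,0.27586
13.946,8.77705,8.33421,8.32929,0.191143,0.256614
14.7196,7.52928,7.10536,7.1002,0.190614,0.238471
15.5362,6.44836,6.04232,6.0369,0.190059,0.221393
16.398,5.52067,5.13153,5.12585,0.189478,0.205342
17.3076,4.73163,4.35844,4.35249,0.18887,0.190275
18.2677,4.06036,3.70221,3.69597,0.188234,0.176151
19.281,3.48912,3.14517,3.13863,0.187568,0.162927
20.3505,2.99952,2.66894,2.66209,0.186873,0.150559
21.4794,2.57716,2.25917,2.25201,0.186146,0.139007
22.6709,2.2188,1.91268,1.90519,0.185387,0.128227
23.9285,1.91463,1.61969,1.61185,0.184595,0.118179
25.2558,1.65634,1.37195,1.36375,0.183769,0.108824
26.6568,1.43692,1.16245,1.15389,0.182908,0.100122
28.1354,1.25041,0.985312,0.976366,0.18201,0.0920369
29.6962,1.0918,0.835533,0.826194,0.181076,0.084533
31.3434,0.954552,0.706615,0.696872,0.180104,0.0775757
33.0821,0.837606,0.597541,0.587381,0.179093,0.0711322
34.9172,0.738335,0.505711,0.495123,0.178042,0.0651709
36.8541,0.653992,0.428409,0.41738,0.176951,0.0596617
38.8984,0.582259,0.363345,0.351864,0.175819,0.0545759
41.0562,0.520687,0.308099,0.296155,0.174645,0.049886
43.3336,0.467837,0.261258,0.248841,0.17343,0.0455659
45.7374,0.422866,0.222005,0.209104,0.172171,0.0415906
48.2745,0.384534,0.189122,0.175728,0.17087,0.0379366
50.9523,0.351641,0.161432,0.147535,0.169525,0.0345814
53.7787,0.323275,0.138042,0.123634,0.168138,0.0315037
56.7619,0.299009,0.118545,0.103619,0.166706,0.0286834
59.9105,0.278188,0.102307,0.0868547,0.165232,0.0261017
63.2338,0.259913,0.0884419,0.0724584,0.163714,0.0237405
66.7415,0.244196,0.076979,0.060459,0.162154,0.0215831
70.4437,0.230626,0.0675217,0.0504612,0.160551,0.0196137
74.3513,0.218853,0.0597321,0.0421282,0.158907,0.0178176
78.4756,0.208583,0.0533296,0.0351805,0.157222,0.0161809
82.8288,0.199398,0.0479051,0.02921,0.155497,0.0146909
87.4234,0.191263,0.0434346,0.0241941,0.153734,0.0133354
92.2729,0.184094,0.0398424,0.0200583,0.151933,0.0121034
97.3913,0.177723,0.0369679,0.0166432,0.150095,0.0109845
102.794,0.171707,0.0343756,0.0135148,0.148224,0.00996908
108.496,0.166361,0.0323856,0.0109943,0.146319,0.00904839
114.514,0.161626,0.0309437,0.00902878,0.144383,0.0082142
120.866,0.157309,0.0298627,0.00743246,0.142417,0.00745896
127.571,0.153324,0.0290597,0.00612353,0.140425,0.00677572
134.648,0.149613,0.0284786,0.00504739,0.138407,0.0061581
142.117,0.146128,0.0280761,0.00416173,0.136366,0.00560023
150,0.142834,0.0278169,0.0034324,0.134305,0.00509671
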