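energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,206.864,205.849,205.847,0.202298,0.815011
5.27736,177.149,176.172,176.17,0.202086,0.777467
5.5701,151.717,150.777,150.775,0.201862,0.740506
5.87908,129.95,129.046,129.044,0.201627,0.704207
6.2052,111.327,110.459,110.457,0.201379,0.668646
6.54941,95.3883,94.5558,94.5533,0.201118,0.633899
6.91271,81.7413,80.943,80.9404,0.200844,0.600036
7.29616,70.0558,69.2909,69.2881,0.200556,0.567122
7.70089,60.0495,59.317,59.3141,0.200253,0.535215
8.12807,51.4744,50.7732,50.7701,0.199934,0.504369
8.57894,44.1187,43.4477,43.4445,0.199599,0.474625
9.05482,37.8217,37.1799,37.1765,0.199247,0.446019
9.55711,32.4307,31.8168,31.8132,0.198878,0.418577
10.0872,27.8164,27.2293,27.2255,0.198535,0.392404
10.6468,23.8689,23.3066,23.3027,0.198382,0.367795
11.2374,20.4815,19.9433,19.9392,0.198141,0.344197
11.8607,17.5749,17.0598,17.0555,0.197806,0.321619
12.5187,15.0807,14.5879,14.5833,0.197366,0.300059
13.2131,12.9406,12.469,12.4642,0.196814,0.279512
13.946,11.1041,10.653,10.648,0.196137,0.259964
14.7196,9.52825,9.09682,9.09153,0.195325,0.241398
15.5362,8.17739,7.76363,7.75807,0.194903,0.224411
16.398,7.01866,6.62133,6.6155,0.194595,0.208569
17.3076,6.02412,5.64265,5.63653,0.194091,0.193495
18.2677,5.17051,4.80438,4.79797,0.193371,0.179169
19.281,4.43785,4.08657,4.07986,0.192414,0.165573
20.3505,3.81669,3.47873,3.4717,0.191809,0.153174
21.4794,3.29642,2.96929,2.96189,0.192193,0.142333
22.6709,2.84707,2.53069,2.52292,0.192228,0.131927
23.9285,2.45898,2.1533,2.14515,0.191874,0.121951
25.2558,2.12379,1.82882,1.82029,0.191091,0.112401
26.6568,1.83428,1.55006,1.54117,0.189838,0.103275
28.1354,1.58425,1.31085,1.3016,0.188076,0.0945681
29.6962,1.36829,1.10582,1.09624,0.185768,0.0862807
31.3434,1.19767,0.94226,0.932209,0.1858,0.0796631
33.0821,1.05159,0.802818,0.792277,0.18581,0.0735015
34.9172,0.923323,0.681779,0.670773,0.185052,0.0674983
36.8541,0.810703,0.576986,0.56555,0.183476,0.0616762
38.8984,0.711819,0.486535,0.474713,0.181047,0.0560591
41.0562,0.631402,0.412724,0.400432,0.179732,0.0512375
43.3336,0.566224,0.352397,0.33954,0.179573,0.0471101
45.7374,0.507774,0.299717,0.286351,0.178376,0.0430466
48.2745,0.455357,0.25395,0.240144,0.17613,0.0390838
50.9523,0.411307,0.215873,0.201594,0.174184,0.0355291
53.7787,0.376538,0.185236,0.170357,0.173636,0.0325458
56.7619,0.344709,0.158509,0.14311,0.171984,0.0296148
59.9105,0.31557,0.135351,0.11952,0.169277,0.0267724
63.2338,0.295582,0.117758,0.101186,0.169742,0.0246532
66.7415,0.27704,0.102572,0.0853404,0.169143,0.0225566
70.4437,0.259661,0.0894051,0.0716014,0.167545,0.0205143
74.3513,0.243372,0.0780589,0.0597752,0.165044,0.0185532
78.4756,0.228106,0.0683422,0.0496714,0.161741,0.0166934
82.8288,0.216615,0.0607043,0.0414698,0.159984,0.0151616
87.4234,0.2072,0.0545576,0.0346965,0.158692,0.0138113
92.2729,0.198194,0.049343,0.0289341,0.156731,0.0125295
97.3913,0.18958,0.0449366,0.0240565,0.154198,0.0113261
102.794,0.182675,0.0413137,0.0198467,0.15253,0.0102976
108.496,0.177263,0.0385674,0.0164282,0.151434,0.00940094
114.514,0.172012,0.0363647,0.0136227,0.149832,0.00855749
120.866,0.166917,0.03457,0.0112825,0.14786,0.00777414
127.571,0.161972,0.0331095,0.00932958,0.145591,0.00705187
134.648,0.157174,0.031926,0.00770351,0.143081,0.00638967
142.117,0.152518,0.0309712,0.006353,0.14038,0.00578542
150,0.148,0.0302039,0.00523385,0.13753,0.00523629
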