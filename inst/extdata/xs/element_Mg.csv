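energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,153.153,152.08,152.078,0.194022,0.881662
5.27736,131.125,130.093,130.091,0.193818,0.840284
5.5701,112.277,111.286,111.283,0.193603,0.799561
5.87908,96.1478,95.197,95.1948,0.193377,0.759586
6.2052,82.24,81.3287,81.3264,0.19314,0.720452
6.54941,70.2988,69.4261,69.4237,0.19289,0.682248
6.91271,60.1007,59.2656,59.2631,0.192627,0.645057
7.29616,51.3908,50.5922,50.5895,0.19235,0.608956
7.70089,43.9514,43.1882,43.1854,0.19206,0.574012
8.12807,37.5688,36.8397,36.8368,0.191754,0.540284
8.57894,32.0632,31.3671,31.364,0.191433,0.507819
9.05482,27.372,26.7075,26.7042,0.191096,0.476653
9.55711,23.3744,22.7402,22.7368,0.190741,0.446809
10.0872,19.9547,19.3497,19.3461,0.190369,0.418304
10.6468,16.9857,16.4084,16.4046,0.189978,0.391138
11.2374,14.4652,13.9143,13.9103,0.189568,0.365308
11.8607,12.3252,11.7995,11.7953,0.189137,0.340797
12.5187,10.5081,10.0063,10.0019,0.188686,0.317584
13.2131,8.96497,8.48573,8.48112,0.188212,0.29564
13.946,7.65425,7.19643,7.1916,0.187716,0.27493
14.7196,6.54076,6.10322,6.09814,0.187196,0.255417
15.5362,5.58231,5.16392,5.1586,0.186651,0.237059
16.398,4.7641,4.36379,4.35821,0.186081,0.219811
17.3076,4.07111,3.68785,3.682,0.185483,0.203629
18.2677,3.48404,3.11684,3.11071,0.184859,0.188464
19.281,2.98654,2.63449,2.62807,0.184205,0.174271
20.3505,2.56218,2.22438,2.21766,0.183522,0.161001
21.4794,2.19807,1.87369,1.86665,0.182808,0.14861
22.6709,1.89032,1.57856,1.5712,0.182063,0.13705
23.9285,1.63008,1.33021,1.32251,0.181285,0.126279
25.2558,1.40991,1.12124,1.11319,0.180474,0.116252
26.6568,1.22355,0.945407,0.936995,0.179628,0.106928
28.1354,1.0657,0.797474,0.788689,0.178747,0.0982675
29.6962,0.931916,0.673027,0.663856,0.177829,0.0902309
31.3434,0.816519,0.566431,0.556863,0.176874,0.0827817
33.0821,0.718506,0.476718,0.46674,0.175881,0.0758843
34.9172,0.635557,0.401601,0.391203,0.174849,0.0695049
36.8541,0.565279,0.338722,0.32789,0.173778,0.0636109
38.8984,0.505663,0.2861,0.274825,0.172666,0.0581715
41.0562,0.454534,0.241593,0.229864,0.171514,0.053157
43.3336,0.410685,0.20402,0.191826,0.17032,0.0485394
45.7374,0.373458,0.172752,0.160083,0.169084,0.0442919
48.2745,0.341787,0.146746,0.133592,0.167806,0.0403889
50.9523,0.314615,0.124971,0.111323,0.166486,0.0368063
53.7787,0.291159,0.106664,0.0925147,0.165123,0.0335212
56.7619,0.271113,0.091543,0.0768841,0.163717,0.030512
59.9105,0.253922,0.0790693,0.0638944,0.162269,0.0277583
63.2338,0.238687,0.068365,0.0526682,0.160779,0.0252407
66.7415,0.225592,0.0596281,0.0434043,0.159246,0.0229412
70.4437,0.214285,0.0525245,0.0357699,0.157672,0.0208428
74.3513,0.204466,0.0467666,0.0294783,0.156058,0.0189297
78.4756,0.195883,0.0421171,0.0242934,0.154403,0.017187
82.8288,0.188068,0.0381183,0.0197584,0.152709,0.0156009
87.4234,0.181089,0.0348486,0.0159531,0.150977,0.0141586
92.2729,0.174937,0.0323101,0.0128808,0.149208,0.012848
97.3913,0.169462,0.0303603,0.0104001,0.147404,0.0116581
102.794,0.163493,0.0278356,0.00734886,0.145566,0.0105786
108.496,0.157865,0.0255771,0.00456929,0.143695,0.0096001
114.514,0.153349,0.024363,0.00284104,0.141794,0.00871377
120.866,0.149542,0.0237945,0.00176647,0.139864,0.00791155
127.571,0.146191,0.0236232,0.00109833,0.137907,0.00718602
134.648,0.143139,0.023694,0.000682908,0.135925,0.00653033
142.117,0.140284,0.0239102,0.00042461,0.133921,0.00593823
150,0.137565,0.0242112,0.000264009,0.131897,0.00540396
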