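energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,40.27,39.6012,39.5993,0.196807,0.473859
5.27736,34.2945,33.6487,33.6468,0.19708,0.450615
5.5701,29.2056,28.5827,28.5806,0.19728,0.427698
5.87908,24.8719,24.2715,24.2693,0.197399,0.405168
6.2052,21.1748,20.5971,20.5948,0.197255,0.382752
6.54941,18.0239,17.4688,17.4663,0.19691,0.360689
6.91271,15.3419,14.8088,14.8062,0.196456,0.339238
7.29616,13.059,12.5474,12.5447,0.195883,0.318439
7.70089,11.1158,10.6252,10.6223,0.195178,0.298324
8.12807,9.46474,8.99437,8.99138,0.194372,0.278986
8.57894,8.06497,7.61407,7.61094,0.193515,0.260518
9.05482,6.87222,6.44026,6.43698,0.192479,0.242766
9.55711,5.85587,5.44232,5.43889,0.191245,0.225737
10.0872,4.99491,4.59844,4.59484,0.190195,0.20988
10.6468,4.28323,3.89923,3.89543,0.19098,0.196827
11.2374,3.67295,3.30143,3.29741,0.191443,0.184097
11.8607,3.14962,2.7906,2.78637,0.191544,0.171708
12.5187,2.70086,2.3544,2.34995,0.191239,0.159672
13.2131,2.31604,1.98221,1.97755,0.190484,0.148003
13.946,1.98605,1.66497,1.6601,0.189233,0.136713
14.7196,1.70307,1.39489,1.38981,0.187442,0.125816
15.5362,1.47641,1.1774,1.17206,0.18751,0.116844
16.398,1.28742,0.996075,0.990432,0.188202,0.108789
17.3076,1.12263,0.839637,0.833705,0.188123,0.1008
18.2677,0.978928,0.705014,0.698807,0.187206,0.092914
19.281,0.853621,0.589513,0.583052,0.185398,0.0851713
20.3505,0.752076,0.49554,0.488771,0.184786,0.0785194
21.4794,0.677178,0.423073,0.415851,0.187633,0.0736943
22.6709,0.609739,0.359366,0.351709,0.18934,0.0686894
23.9285,0.549016,0.303683,0.29562,0.189828,0.0635681
25.2558,0.49434,0.255325,0.246892,0.189049,0.0583988
26.6568,0.445109,0.213616,0.20486,0.186997,0.0532525
28.1354,0.400781,0.177905,0.168876,0.183706,0.0481992
29.6962,0.360868,0.147557,0.138313,0.17925,0.0433044
31.3434,0.335269,0.12535,0.115629,0.179691,0.0399494
33.0821,0.313762,0.106852,0.0966256,0.180273,0.0368634
34.9172,0.293634,0.0909153,0.0802322,0.179634,0.0337687
36.8541,0.274798,0.0773079,0.0662227,0.177853,0.0307219
38.8984,0.25717,0.0657872,0.0543572,0.175041,0.0277714
41.0562,0.24339,0.0565712,0.0447116,0.173417,0.025261
43.3336,0.233136,0.0492755,0.0368812,0.173111,0.0231436
45.7374,0.223314,0.0431714,0.030288,0.171936,0.0210904
48.2745,0.213906,0.0381039,0.0247776,0.170001,0.0191278
50.9523,0.205779,0.0339848,0.0201944,0.168226,0.0173583
53.7787,0.199552,0.0307381,0.0164001,0.167322,0.0158304
56.7619,0.193515,0.0281368,0.0132877,0.165842,0.0143849
59.9105,0.187659,0.0260721,0.0107463,0.163882,0.0130312
63.2338,0.183419,0.0244103,0.00849244,0.163042,0.0118846
66.7415,0.179315,0.0231938,0.00671059,0.161793,0.0108118
70.4437,0.175303,0.0223292,0.00530806,0.160181,0.009814
74.3513,0.17138,0.0217394,0.00420467,0.158283,0.00889282
78.4756,0.167546,0.0213632,0.00333644,0.156162,0.00804736
82.8288,0.164255,0.020652,0.00202832,0.154903,0.00732394
87.4234,0.161278,0.0207056,0.00154573,0.153089,0.00664363
92.2729,0.158356,0.0209118,0.00123635,0.151098,0.00602145
97.3913,0.155486,0.0211757,0.000994737,0.149034,0.005457
102.794,0.152766,0.0214163,0.000713469,0.147101,0.00495217
108.496,0.150187,0.0217587,0.000537739,0.145153,0.00449627
114.514,0.147651,0.0221603,0.000435061,0.143133,0.00408314
120.866,0.145158,0.0225786,0.000357319,0.141091,0.00371036
127.571,0.142707,0.0230041,0.000294382,0.139038,0.00337451
134.648,0.140298,0.0234328,0.000242708,0.136983,0.00307225
142.117,0.137929,0.0238624,0.000200162,0.134928,0.00280048
150,0.1356,0.0242906,0.000165107,0.132879,0.00255635
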