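energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,418.905,417.38,417.378,0.188451,1.33806
5.27736,359.298,357.832,357.83,0.188253,1.27961
5.5701,308.188,306.78,306.778,0.188044,1.2218
5.87908,264.362,263.011,263.009,0.187825,1.16474
6.2052,226.627,225.333,225.331,0.187594,1.10856
6.54941,194.211,192.972,192.97,0.187351,1.05339
6.91271,166.443,165.259,165.257,0.187096,0.999362
7.29616,142.657,141.526,141.523,0.186827,0.946593
7.70089,122.28,121.201,121.199,0.186545,0.895202
8.12807,104.789,103.761,103.758,0.186248,0.845295
8.57894,89.7383,88.7584,88.7554,0.185936,0.796968
9.05482,76.8581,75.9254,75.9222,0.185608,0.750302
9.55711,65.8352,64.9479,64.9445,0.185264,0.705365
10.0872,56.3896,55.546,55.5425,0.184903,0.662209
10.6468,48.2547,47.453,47.4493,0.184523,0.620869
11.2374,41.301,40.5393,40.5355,0.184125,0.581368
11.8607,35.3565,34.6331,34.629,0.183707,0.543712
12.5187,30.2744,29.5875,29.5832,0.183268,0.507893
13.2131,25.9294,25.2771,25.2726,0.182808,0.473895
13.946,22.2142,21.5949,21.5902,0.182326,0.441688
14.7196,19.0373,18.4492,18.4443,0.181821,0.411233
15.5362,16.2792,15.7206,15.7154,0.181292,0.382484
16.398,13.9076,13.3769,13.3714,0.180737,0.35539
17.3076,11.8871,11.3827,11.3771,0.180157,0.329894
18.2677,10.1656,9.68611,9.68015,0.17955,0.305935
19.281,8.69871,8.24258,8.23634,0.178916,0.283452
20.3505,7.44006,7.00596,6.99943,0.178252,0.262379
21.4794,6.35337,5.93999,5.93316,0.177559,0.242652
22.6709,5.43036,5.03647,5.02932,0.176835,0.224206
23.9285,4.64622,4.27065,4.26317,0.17608,0.206978
25.2558,3.97992,3.62155,3.61373,0.175292,0.190904
26.6568,3.41362,3.0714,3.06322,0.17447,0.175923
28.1354,2.93217,2.60512,2.59658,0.173614,0.161975
29.6962,2.52275,2.20993,2.20103,0.172723,0.149004
31.3434,2.1692,1.86974,1.86045,0.171795,0.136953
33.0821,1.86813,1.58123,1.57153,0.170831,0.125769
34.9172,1.61271,1.33759,1.32749,0.169829,0.1154
36.8541,1.39592,1.13186,1.12134,0.168788,0.105798
38.8984,1.21182,0.958152,0.947201,0.167708,0.0969156
41.0562,1.05436,0.810457,0.799064,0.166589,0.0887078
43.3336,0.919715,0.684998,0.673154,0.165429,0.0811317
45.7374,0.805458,0.579389,0.567083,0.164229,0.0741464
48.2745,0.708427,0.490503,0.477726,0.162988,0.0677128
50.9523,0.625634,0.415391,0.402135,0.161705,0.0617938
53.7787,0.554748,0.351755,0.338012,0.160381,0.0563541
56.7619,0.49449,0.298352,0.284114,0.159016,0.0513603
59.9105,0.4432,0.253549,0.23881,0.15761,0.0467804
63.2338,0.398897,0.215397,0.20015,0.156162,0.0425844
66.7415,0.361153,0.183493,0.167735,0.154674,0.0387441
70.4437,0.328947,0.156843,0.14057,0.153145,0.0352326
74.3513,0.301406,0.134596,0.117804,0.151577,0.0320249
78.4756,0.277792,0.116037,0.0987254,0.149969,0.0290973
82.8288,0.25721,0.100291,0.0824581,0.148324,0.0264279
87.4234,0.239381,0.0870957,0.0687428,0.146642,0.0239959
92.2729,0.224015,0.0761802,0.0573087,0.144924,0.0217822
97.3913,0.210717,0.0671636,0.0477765,0.143171,0.0197688
102.794,0.198877,0.0594502,0.0395517,0.141386,0.0179392
108.496,0.18837,0.0529281,0.0325235,0.139569,0.0162778
114.514,0.179237,0.0476482,0.0267442,0.137722,0.0147705
120.866,0.171244,0.0433874,0.0219918,0.135848,0.0134039
127.571,0.164197,0.0399621,0.018084,0.133947,0.012166
134.648,0.157938,0.0372209,0.0148705,0.132022,0.0110454
142.117,0.152336,0.0350393,0.0122281,0.130076,0.0100318
150,0.14728,0.0333148,0.0100552,0.128109,0.00911569
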