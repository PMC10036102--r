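energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,47.1,46.3792,46.3773,0.1965,0.526193
5.27736,39.9313,39.2375,39.2356,0.196293,0.499481
5.5701,33.863,33.1957,33.1936,0.196076,0.473367
5.87908,28.7258,28.0842,28.082,0.195847,0.44791
6.2052,24.4078,23.7913,23.789,0.195607,0.423164
6.54941,20.7629,20.1708,20.1684,0.195353,0.399177
6.91271,17.6699,17.1014,17.0988,0.195087,0.375992
7.29616,15.0449,14.4991,14.4964,0.194807,0.353646
7.70089,12.8168,12.2929,12.2901,0.194513,0.332165
8.12807,10.9241,10.4213,10.4183,0.194203,0.31157
8.57894,9.31463,8.83202,8.82888,0.193878,0.291874
9.05482,7.94857,7.48526,7.48195,0.193536,0.273083
9.55711,6.78889,6.34398,6.34051,0.193177,0.255197
10.0872,5.79797,5.37061,5.36696,0.1928,0.238207
10.6468,4.92989,4.51922,4.51539,0.192404,0.222101
11.2374,4.19778,3.80296,3.79893,0.191989,0.206861
11.8607,3.58018,3.20039,3.19616,0.191553,0.192468
12.5187,3.05902,2.69347,2.68903,0.191096,0.178895
13.2131,2.61909,2.26702,2.26236,0.190616,0.166117
13.946,2.24761,1.90829,1.90339,0.190114,0.154103
14.7196,1.93379,1.60652,1.60138,0.189587,0.142824
15.5362,1.6651,1.3492,1.34382,0.189035,0.132247
16.398,1.43691,1.13176,1.12611,0.188457,0.122343
17.3076,1.24461,0.949603,0.94368,0.187852,0.113078
18.2677,1.08244,0.797008,0.790801,0.187219,0.104421
19.281,0.945588,0.669191,0.662689,0.186558,0.0963408
20.3505,0.829054,0.561189,0.55438,0.185866,0.0888077
21.4794,0.729035,0.469227,0.4621,0.185143,0.0817917
22.6709,0.644833,0.392637,0.38518,0.184388,0.0752642
23.9285,0.573863,0.328864,0.321065,0.183601,0.0691976
25.2558,0.513966,0.275774,0.267621,0.182779,0.0635654
26.6568,0.463338,0.231593,0.223074,0.181922,0.058342
28.1354,0.420475,0.194839,0.185942,0.18103,0.0535029
29.6962,0.384116,0.164279,0.154991,0.1801,0.0490248
31.3434,0.35237,0.138042,0.128351,0.179133,0.0448852
33.0821,0.325319,0.116234,0.106129,0.178128,0.0410628
34.9172,0.302374,0.0982858,0.0877544,0.177083,0.0375371
36.8541,0.282847,0.0835305,0.072561,0.175997,0.0342886
38.8984,0.266169,0.071417,0.0599982,0.174872,0.0312989
41.0562,0.251634,0.0612584,0.0493792,0.173704,0.0285503
43.3336,0.238958,0.0527869,0.0404366,0.172495,0.0260259
45.7374,0.228067,0.045945,0.0331136,0.171244,0.0237101
48.2745,0.218654,0.040439,0.0271167,0.169949,0.0215876
50.9523,0.210376,0.0359416,0.0221195,0.168612,0.0196443
53.7787,0.203011,0.0322431,0.0179128,0.167232,0.0178669
56.7619,0.196557,0.0293522,0.0145061,0.165808,0.0162427
59.9105,0.190849,0.0271161,0.0117473,0.164341,0.0147599
63.2338,0.185481,0.025139,0.00924168,0.162832,0.0134074
66.7415,0.180719,0.0236955,0.00726451,0.16128,0.0121748
70.4437,0.176449,0.0226789,0.00571034,0.159686,0.0110525
74.3513,0.172571,0.0219977,0.00448867,0.158051,0.0100315
78.4756,0.169007,0.0215797,0.00352836,0.156375,0.00910344
82.8288,0.165541,0.0212157,0.00262133,0.154659,0.00826049
87.4234,0.162288,0.0210244,0.00188757,0.152905,0.00749547
92.2729,0.159275,0.0210367,0.00135921,0.151114,0.00680172
97.3913,0.156438,0.0211939,0.000978739,0.149287,0.00617309
102.794,0.153359,0.0210784,0.00032997,0.147425,0.0056039
108.496,0.150673,0.0213298,5.37182e-05,0.14553,0.00508893
114.514,0.148237,0.0218056,8.74516e-06,0.143605,0.00462336
120.866,0.145854,0.0223108,1.42369e-06,0.14165,0.00420277
127.571,0.143492,0.0228128,2.31772e-07,0.139668,0.00382311
134.648,0.141142,0.023305,3.77318e-08,0.137661,0.00348068
142.117,0.138804,0.0237856,6.14262e-09,0.135632,0.00317206
150,0.136475,0.0242531,1e-09,0.133581,0.00289416
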