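energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,41.87,41.1802,41.1781,0.218048,0.473805
5.27736,35.5307,34.8649,34.8627,0.21798,0.449972
5.5701,30.1511,29.5091,29.5068,0.217831,0.426529
5.87908,25.5861,24.9674,24.9649,0.217595,0.403532
6.2052,21.7977,21.2004,21.1978,0.217835,0.382045
6.54941,18.6145,18.0373,18.0346,0.218315,0.361579
6.91271,15.8961,15.3387,15.3359,0.218675,0.341539
7.29616,13.5747,13.0369,13.0338,0.2189,0.321972
7.70089,11.5923,11.0736,11.0704,0.21897,0.302917
8.12807,9.89009,9.39059,9.38723,0.218689,0.284174
8.57894,8.41875,7.93899,7.93546,0.217783,0.265509
9.05482,7.1663,6.70579,6.7021,0.216664,0.247538
9.55711,6.10017,5.65846,5.65459,0.215309,0.23027
10.0872,5.19835,4.77407,4.77002,0.214155,0.214174
10.6468,4.45525,4.04347,4.03919,0.215101,0.20096
11.2374,3.81837,3.41918,3.41465,0.21567,0.188046
11.8607,3.27253,2.88604,2.88127,0.215811,0.175451
12.5187,2.80472,2.43107,2.42606,0.21547,0.16319
13.2131,2.40379,2.04317,2.03792,0.214593,0.151276
13.946,2.06017,1.71281,1.70732,0.213122,0.139725
14.7196,1.76567,1.43182,1.42611,0.211006,0.128553
15.5362,1.53113,1.20666,1.20065,0.21108,0.119408
16.398,1.33616,1.01941,1.01306,0.211882,0.111212
17.3076,1.16601,0.85787,0.851193,0.211762,0.103051
18.2677,1.01752,0.7189,0.711917,0.210641,0.0949669
19.281,0.88795,0.599753,0.592488,0.208455,0.0870075
20.3505,0.78339,0.50317,0.495564,0.207645,0.0801813
21.4794,0.70724,0.429223,0.421106,0.210859,0.075275
22.6709,0.638492,0.364192,0.355589,0.212739,0.0701643
23.9285,0.576427,0.307367,0.298311,0.213197,0.0649188
25.2558,0.520395,0.258057,0.248592,0.212189,0.0596142
26.6568,0.46981,0.215585,0.205764,0.209718,0.0543283
28.1354,0.424142,0.179285,0.169169,0.205836,0.049137
29.6962,0.382913,0.148507,0.13816,0.200641,0.0441111
31.3434,0.356843,0.126086,0.115215,0.200962,0.0406663
33.0821,0.335011,0.107473,0.0960438,0.201463,0.0375039
34.9172,0.314514,0.0914823,0.0795509,0.200623,0.0343401
36.8541,0.295272,0.0778715,0.0654969,0.198542,0.0312325
38.8984,0.277206,0.0663848,0.0536288,0.195348,0.0282296
41.0562,0.263099,0.0572266,0.0439981,0.193433,0.0256682
43.3336,0.252645,0.0500068,0.036192,0.19295,0.0235029
45.7374,0.242605,0.0439919,0.0296385,0.191555,0.0214114
48.2745,0.232965,0.0390214,0.0241768,0.189369,0.0194185
50.9523,0.224631,0.0350232,0.0196654,0.187346,0.0176199
53.7787,0.218263,0.031921,0.015962,0.186239,0.0160622
56.7619,0.212076,0.0294451,0.0129198,0.184561,0.0145947
59.9105,0.206064,0.027491,0.0104328,0.182406,0.0132245
63.2338,0.201658,0.0259433,0.00823644,0.181366,0.012055
66.7415,0.197386,0.0248167,0.00648508,0.179936,0.0109652
70.4437,0.193205,0.0240284,0.00509753,0.178153,0.0099545
74.3513,0.189113,0.0235088,0.00400149,0.176088,0.00902302
78.4756,0.185107,0.0232007,0.00313781,0.1738,0.00816894
82.8288,0.181612,0.0229944,0.00233086,0.171869,0.00741203
87.4234,0.178416,0.0229564,0.00167926,0.170007,0.00672963
92.2729,0.175276,0.0230801,0.00120882,0.167961,0.00610546
97.3913,0.172191,0.0233187,0.000869679,0.165784,0.00553701
102.794,0.169245,0.0233632,0.000293564,0.163918,0.00503342
108.496,0.166431,0.0237041,4.77912e-05,0.161811,0.00457166
114.514,0.163663,0.0242181,7.77222e-06,0.159505,0.00414995
120.866,0.160941,0.0247551,1.26398e-06,0.157171,0.00376938
127.571,0.158265,0.0252905,2.05595e-07,0.154838,0.00342681
134.648,0.155633,0.0258195,3.34485e-08,0.152514,0.00311877
142.117,0.153045,0.026341,5.44305e-09,0.150203,0.00284199
150,0.1505,0.026854,8.85958e-10,0.147906,0.00259351
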