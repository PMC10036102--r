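energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,41.8424,41.1672,41.1651,0.216122,0.461177
5.27736,35.4991,34.8478,34.8456,0.215894,0.437614
5.5701,30.1275,29.4996,29.4973,0.215655,0.4146
5.87908,25.5782,24.973,24.9706,0.215404,0.392183
6.2052,21.76,21.177,21.1744,0.215139,0.370409
6.54941,18.5378,17.9763,17.9737,0.214861,0.349318
6.91271,15.8004,15.2597,15.2569,0.214568,0.328946
7.29616,13.4745,12.9538,12.9509,0.21426,0.309323
7.70089,11.4979,10.9967,10.9935,0.213936,0.29047
8.12807,9.81575,9.33303,9.32975,0.213596,0.272403
8.57894,8.38136,7.91645,7.91299,0.213238,0.255133
9.05482,7.16298,6.71509,6.71146,0.212862,0.238663
9.55711,6.12789,5.69625,5.69243,0.212467,0.222991
10.0872,5.24323,4.82708,4.82307,0.212053,0.20811
10.6468,4.46964,4.06823,4.06401,0.211617,0.194007
11.2374,3.81635,3.42896,3.42453,0.21116,0.180666
11.8607,3.2645,2.8904,2.88575,0.210681,0.168069
12.5187,2.79819,2.4367,2.43182,0.210178,0.156194
13.2131,2.40402,2.05448,2.04935,0.209651,0.145015
13.946,2.0707,1.73248,1.7271,0.209098,0.134508
14.7196,1.78872,1.46121,1.45556,0.208518,0.124644
15.5362,1.54681,1.22943,1.2235,0.207911,0.115398
16.398,1.34102,1.03322,1.027,0.207276,0.10674
17.3076,1.16735,0.868612,0.862097,0.206611,0.0986432
18.2677,1.02069,0.730521,0.723694,0.205915,0.0910791
19.281,0.896739,0.614684,0.607532,0.205187,0.0840205
20.3505,0.791017,0.516639,0.50915,0.204426,0.0774407
21.4794,0.700108,0.433002,0.425163,0.203631,0.0713138
22.6709,0.623463,0.363249,0.355048,0.202801,0.0656147
23.9285,0.558764,0.305088,0.29651,0.201934,0.060319
25.2558,0.504071,0.256604,0.247637,0.201031,0.0554034
26.6568,0.457763,0.216199,0.206829,0.200088,0.0508454
28.1354,0.418485,0.182541,0.172755,0.199107,0.0466236
29.6962,0.385104,0.154517,0.144302,0.198084,0.0427175
31.3434,0.355902,0.130432,0.119774,0.197021,0.0391072
33.0821,0.330967,0.110392,0.099278,0.195915,0.0357742
34.9172,0.309763,0.0938807,0.0822976,0.194765,0.0327003
36.8541,0.291669,0.0802933,0.0682285,0.193572,0.0298687
38.8984,0.276167,0.0691295,0.0565704,0.192334,0.0272629
41.0562,0.262619,0.0597668,0.0467013,0.19105,0.0248676
43.3336,0.250766,0.0519618,0.0383783,0.18972,0.0226681
45.7374,0.240539,0.0456581,0.0315453,0.188343,0.0206504
48.2745,0.231656,0.0405871,0.0259346,0.18692,0.0188015
50.9523,0.223799,0.0364436,0.0212413,0.185449,0.0171089
53.7787,0.216768,0.0330381,0.0172768,0.183931,0.0155609
56.7619,0.210572,0.0303891,0.0140605,0.182365,0.0141464
59.9105,0.205057,0.0283527,0.0114493,0.180752,0.0128553
63.2338,0.199711,0.0264269,0.00894205,0.179092,0.0116777
66.7415,0.195113,0.0251955,0.00712384,0.177385,0.0106046
70.4437,0.19095,0.0243535,0.00569052,0.175632,0.00962765
74.3513,0.187122,0.0238078,0.00455033,0.173833,0.00873894
78.4756,0.183563,0.0234959,0.00364196,0.17199,0.00793116
82.8288,0.18008,0.0232304,0.0027793,0.170103,0.00719755
87.4234,0.176808,0.0231496,0.00210184,0.168174,0.00653182
92.2729,0.173731,0.0232421,0.00159965,0.166204,0.00592816
97.3913,0.170799,0.0234575,0.00122376,0.164194,0.00538122
102.794,0.167703,0.0234907,0.00067043,0.162146,0.00488604
108.496,0.164895,0.0237954,0.000394782,0.160062,0.00443807
114.514,0.162276,0.0242719,0.000298525,0.157945,0.00403311
120.866,0.159703,0.0247782,0.00024101,0.155795,0.00366732
127.571,0.15715,0.0252879,0.000197415,0.153615,0.00333717
134.648,0.154609,0.0257944,0.000162244,0.151408,0.00303942
142.117,0.15208,0.0262941,0.000133459,0.149175,0.0027711
150,0.149559,0.0267847,0.000109817,0.14692,0.00252952
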