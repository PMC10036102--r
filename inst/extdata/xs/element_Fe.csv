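energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,140,137.601,137.599,0.182959,2.21764
5.27736,120.314,118.003,118.002,0.182767,2.12922
5.5701,103.419,101.197,101.195,0.182564,2.04129
5.87908,88.9184,86.7841,86.782,0.182351,1.95402
6.2052,76.3583,74.3108,74.3086,0.182127,1.86757
6.54941,65.5334,63.5717,63.5694,0.181892,1.78213
6.91271,56.2618,54.3846,54.3822,0.181644,1.69787
7.10844,52.0008,50.1669,50.1644,0.181511,1.65483
7.11556,409.999,408.167,408.164,0.181506,1.65329
7.29616,384.848,383.054,383.051,0.181383,1.615
7.70089,335.8,334.088,334.086,0.181109,1.5337
8.12807,292.638,291.006,291.003,0.180821,1.45416
8.57894,254.248,252.694,252.691,0.180518,1.37655
9.05482,220.905,219.427,219.424,0.1802,1.30106
9.55711,191.943,190.539,190.536,0.179866,1.22782
10.0872,166.637,165.304,165.3,0.179514,1.15698
10.6468,143.996,142.731,142.728,0.179146,1.08864
11.2374,124.439,123.241,123.238,0.178759,1.02291
11.8607,107.547,106.413,106.409,0.178353,0.959838
12.5187,92.9555,91.8822,91.8781,0.177927,0.899481
13.2131,80.351,79.336,79.3317,0.177481,0.841859
13.946,69.4625,68.5031,68.4985,0.177013,0.786976
14.7196,60.056,59.1495,59.1447,0.176522,0.734813
15.5362,51.7636,50.9073,50.9023,0.176009,0.685339
16.398,44.546,43.7373,43.732,0.175471,0.638503
17.3076,38.3409,37.5773,37.5717,0.174907,0.594245
18.2677,33.0061,32.285,32.2793,0.174318,0.552493
19.281,28.4192,27.7383,27.7323,0.173702,0.513166
20.3505,24.4411,23.7983,23.7919,0.173058,0.476179
21.4794,20.9641,20.3569,20.3503,0.172385,0.44144
22.6709,17.987,17.4134,17.4064,0.171682,0.408856
23.9285,15.4378,14.8957,14.8885,0.170949,0.37833
25.2558,13.2547,12.7424,12.7348,0.170184,0.349766
26.6568,11.385,10.9005,10.8926,0.169386,0.323069
28.1354,9.78361,9.32519,9.31691,0.168555,0.298144
29.6962,8.41174,7.9778,7.96915,0.16769,0.274898
31.3434,7.21417,6.80316,6.79413,0.166789,0.253242
33.0821,6.18691,5.79738,5.78797,0.165853,0.233088
34.9172,5.31005,4.94062,4.93082,0.16488,0.214352
36.8541,4.56142,4.21081,4.2006,0.16387,0.196952
38.8984,3.92215,3.58915,3.57852,0.162821,0.18081
41.0562,3.3724,3.05588,3.04482,0.161734,0.165851
43.3336,2.8999,2.59879,2.58729,0.160609,0.152004
45.7374,2.49716,2.21046,2.19851,0.159443,0.1392
48.2745,2.15377,1.88056,1.86816,0.158238,0.127373
50.9523,1.85988,1.59929,1.58642,0.156993,0.116461
53.7787,1.60768,1.35891,1.34557,0.155708,0.106405
56.7619,1.39281,1.15511,1.14128,0.154382,0.0971459
59.9105,1.20966,0.982323,0.968013,0.153017,0.0886312
63.2338,1.05189,0.834269,0.819467,0.151611,0.0808091
66.7415,0.917476,0.708977,0.693679,0.150166,0.0736309
70.4437,0.802931,0.602998,0.587199,0.148682,0.0670503
74.3513,0.705247,0.513366,0.497063,0.14716,0.0610237
78.4756,0.621873,0.437571,0.420764,0.145599,0.0555099
82.8288,0.550182,0.373024,0.355711,0.144002,0.05047
87.4234,0.488734,0.318315,0.300497,0.142369,0.0458677
92.2729,0.436224,0.272176,0.253854,0.140701,0.0416688
97.3913,0.391292,0.233273,0.214451,0.138999,0.0378413
102.794,0.352558,0.200255,0.180936,0.137266,0.0343555
108.496,0.319161,0.172285,0.152475,0.135502,0.0311836
114.514,0.290499,0.148786,0.128491,0.133709,0.0282996
120.866,0.265848,0.129051,0.108279,0.131889,0.0256796
127.571,0.244592,0.112487,0.0912469,0.130044,0.0233013
134.648,0.226213,0.0985928,0.0768938,0.128175,0.0211441
142.117,0.210273,0.0869449,0.0647984,0.126285,0.0191889
150,0.1964,0.0771874,0.0546056,0.124376,0.0174183
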