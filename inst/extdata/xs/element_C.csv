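energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,18.7,18.1466,18.1447,0.196308,0.359015
5.27736,15.6589,15.125,15.123,0.196101,0.339827
5.5701,13.1216,12.6066,12.6046,0.195884,0.321163
5.87908,11.0042,10.5077,10.5055,0.195656,0.30306
6.2052,9.33683,8.85817,8.85586,0.195415,0.285552
6.54941,7.98052,7.51912,7.51669,0.195162,0.268666
6.91271,6.82734,6.38258,6.38002,0.194896,0.252424
7.29616,5.8467,5.41794,5.41524,0.194617,0.236843
7.70089,5.01261,4.59919,4.59635,0.194322,0.221935
8.12807,4.29517,3.89644,3.89346,0.194013,0.207704
8.57894,3.67,3.2853,3.28216,0.193688,0.194151
9.05482,3.14146,2.77014,2.76684,0.193347,0.181271
9.55711,2.69448,2.3359,2.33243,0.192988,0.169056
10.0872,2.31376,1.9673,1.96365,0.192612,0.157494
10.6468,1.9807,1.64575,1.64192,0.192216,0.146569
11.2374,1.70096,1.37692,1.37289,0.191801,0.136263
11.8607,1.46587,1.15218,1.14795,0.191366,0.126558
12.5187,1.2682,0.964302,0.959863,0.190909,0.11743
13.2131,1.10188,0.807253,0.802594,0.19043,0.108857
13.946,0.961836,0.675982,0.671092,0.189928,0.100817
14.7196,0.843823,0.566268,0.561136,0.189401,0.0932854
15.5362,0.742551,0.472845,0.467462,0.18885,0.0862382
16.398,0.656577,0.394298,0.388653,0.188273,0.079652
17.3076,0.584301,0.329047,0.32313,0.187669,0.0735032
18.2677,0.523458,0.274854,0.268653,0.187036,0.0677692
19.281,0.472163,0.229856,0.223361,0.186375,0.0624275
20.3505,0.428232,0.191893,0.185091,0.185684,0.0574566
21.4794,0.39011,0.159433,0.152313,0.184962,0.0528356
22.6709,0.358092,0.132789,0.125339,0.184208,0.0485444
23.9285,0.331127,0.110934,0.103143,0.183421,0.0445638
25.2558,0.308352,0.0930218,0.0848769,0.1826,0.0408752
26.6568,0.289051,0.0783566,0.0698458,0.181744,0.0374608
28.1354,0.272633,0.0663654,0.0574767,0.180853,0.0343038
29.6962,0.25861,0.0565768,0.047298,0.179924,0.031388
31.3434,0.245958,0.047983,0.038302,0.178958,0.0286978
33.0821,0.235074,0.0409968,0.0309016,0.177953,0.0262186
34.9172,0.225777,0.0354522,0.024931,0.176909,0.0239363
36.8541,0.217777,0.0310728,0.020114,0.175825,0.0218376
38.8984,0.210838,0.0276354,0.0162277,0.174701,0.0199096
41.0562,0.204592,0.0247845,0.0129169,0.173534,0.0181405
43.3336,0.198979,0.0224722,0.010134,0.172326,0.0165187
45.7374,0.19406,0.0207696,0.0079507,0.171076,0.0150335
48.2745,0.189696,0.019547,0.00623776,0.169783,0.0136748
50.9523,0.185658,0.018587,0.00477843,0.168447,0.0124329
53.7787,0.181868,0.0178177,0.00350143,0.167068,0.0112989
56.7619,0.178476,0.0173973,0.0025657,0.165646,0.0102644
59.9105,0.175382,0.0172338,0.00188003,0.164181,0.0093214
63.2338,0.171269,0.0160155,0.000133733,0.162673,0.00846263
66.7415,0.168812,0.0164238,8.9025e-06,0.161122,0.00768121
70.4437,0.166501,0.0169525,5.92631e-07,0.15953,0.00697077
74.3513,0.164222,0.017492,3.94509e-08,0.157896,0.00632538
78.4756,0.161961,0.0180337,2.62621e-09,0.156222,0.00573956
82.8288,0.159716,0.0185762,1e-09,0.154508,0.00520822
87.4234,0.157482,0.0191181,1e-09,0.152756,0.00472667
92.2729,0.155257,0.0196582,1e-09,0.150966,0.00429058
97.3913,0.153037,0.0201953,1e-09,0.149141,0.00389597
102.794,0.15082,0.0207281,1e-09,0.147281,0.00353914
108.496,0.148605,0.0212553,1e-09,0.145388,0.00321674
114.514,0.14639,0.0217755,1e-09,0.143464,0.00292567
120.866,0.144175,0.0222876,1e-09,0.141512,0.00266308
127.571,0.141958,0.0227902,1e-09,0.139532,0.00242639
134.648,0.13974,0.0232822,1e-09,0.137527,0.00221321
142.117,0.13752,0.0237623,1e-09,0.135499,0.00202137
150,0.135299,0.0242294,1e-09,0.13345,0.00184889
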