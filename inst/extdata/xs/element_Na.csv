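energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,118.817,117.867,117.865,0.188026,0.763402
5.27736,101.5,100.588,100.586,0.187829,0.726946
5.5701,86.7182,85.8414,85.8394,0.187621,0.691117
5.87908,74.0984,73.2571,73.255,0.187402,0.655997
6.2052,63.2783,62.4717,62.4695,0.187172,0.621667
6.54941,54.0233,53.2505,53.2482,0.186929,0.588203
6.91271,46.1304,45.3905,45.388,0.186675,0.555677
7.29616,39.3987,38.6907,38.6881,0.186407,0.524152
7.70089,33.657,32.9799,32.9772,0.186125,0.493685
8.12807,28.7419,28.0946,28.0917,0.185829,0.464321
8.57894,24.5157,23.8971,23.8941,0.185518,0.436097
9.05482,20.9179,20.3268,20.3236,0.185191,0.40904
9.55711,17.8548,17.2901,17.2867,0.184847,0.383167
10.0872,15.2353,14.6959,14.6924,0.184486,0.358484
10.6468,12.9566,12.4412,12.4375,0.184108,0.33499
11.2374,11.0251,10.5325,10.5287,0.18371,0.312675
11.8607,9.38765,8.91688,8.91283,0.183293,0.291524
12.5187,7.99933,7.54921,7.54496,0.182855,0.271512
13.2131,6.82203,6.39148,6.38702,0.182397,0.252611
13.946,5.8235,5.41147,5.40679,0.181915,0.234789
14.7196,4.97642,4.58192,4.577,0.181411,0.218011
15.5362,4.24827,3.8703,3.86515,0.180883,0.202238
16.398,3.62751,3.26515,3.25975,0.18033,0.187429
17.3076,3.10247,2.75484,2.74917,0.179752,0.173545
18.2677,2.65826,2.32451,2.31857,0.179146,0.160542
19.281,2.2823,1.96163,1.95541,0.178513,0.14838
20.3505,1.96185,1.6535,1.64698,0.177851,0.137016
21.4794,1.68697,1.39022,1.3834,0.177159,0.12641
22.6709,1.45496,1.16914,1.162,0.176437,0.116522
23.9285,1.25903,0.983496,0.976034,0.175683,0.107314
25.2558,1.09347,0.82763,0.819829,0.174897,0.0987464
26.6568,0.953485,0.696775,0.688623,0.174077,0.0907844
28.1354,0.835032,0.58693,0.578416,0.173223,0.0833928
29.6962,0.734718,0.494734,0.485846,0.172334,0.0765379
31.3434,0.648017,0.415693,0.40642,0.171409,0.0701876
33.0821,0.574412,0.349324,0.339655,0.170446,0.0643112
34.9172,0.512183,0.293935,0.283857,0.169446,0.0588793
36.8541,0.459498,0.247723,0.237226,0.168408,0.0538637
38.8984,0.414824,0.209182,0.198255,0.167331,0.0492376
41.0562,0.376437,0.176615,0.165248,0.166214,0.0449755
43.3336,0.343454,0.149162,0.137345,0.165057,0.041053
45.7374,0.315459,0.126431,0.114153,0.163859,0.0374469
48.2745,0.291634,0.107625,0.0948775,0.162621,0.0341352
50.9523,0.271139,0.0919268,0.0787008,0.161341,0.0310972
53.7787,0.253375,0.0787543,0.0650419,0.16002,0.0283129
56.7619,0.238175,0.0679595,0.0537536,0.158658,0.0257638
59.9105,0.225111,0.0591304,0.0444244,0.157255,0.0234323
63.2338,0.213366,0.0514659,0.0362541,0.15581,0.0213018
66.7415,0.203258,0.0452982,0.0295758,0.154325,0.0193569
70.4437,0.194511,0.0403645,0.0241277,0.1528,0.0175829
74.3513,0.186885,0.0364372,0.0196832,0.151235,0.0159663
78.4756,0.180183,0.0333303,0.0160574,0.149632,0.0144944
82.8288,0.173954,0.0306011,0.0128086,0.14799,0.0131554
87.4234,0.168341,0.0284025,0.0100908,0.146312,0.0119382
92.2729,0.16338,0.0267787,0.00794977,0.144598,0.0108328
97.3913,0.158942,0.0256064,0.00626298,0.142849,0.00982954
102.794,0.153763,0.0236294,0.00377571,0.141068,0.00891979
108.496,0.149111,0.0221195,0.0017609,0.139255,0.00809546
114.514,0.145583,0.0216782,0.000821246,0.137412,0.00734909
120.866,0.142599,0.0217304,0.00038301,0.135542,0.00667382
127.571,0.139887,0.0220074,0.000178627,0.133645,0.00606336
134.648,0.13732,0.0223833,8.33076e-05,0.131725,0.00551189
142.117,0.134836,0.0227987,3.88527e-05,0.129783,0.00501411
150,0.132404,0.0232254,1.812e-05,0.127821,0.00456514
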