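energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,193.4,192.259,192.257,0.189336,0.953913
5.27736,165.92,164.823,164.821,0.189137,0.909863
5.5701,142.356,141.303,141.301,0.188928,0.866458
5.87908,122.149,121.139,121.137,0.188708,0.823794
6.2052,104.632,103.664,103.662,0.188476,0.781971
6.54941,89.5397,88.6127,88.6103,0.188232,0.741085
6.91271,76.6334,75.7467,75.7442,0.187975,0.701228
7.29616,65.5964,64.7488,64.7462,0.187705,0.662484
7.70089,56.1574,55.3478,55.3451,0.187422,0.624929
8.12807,48.0427,47.2698,47.267,0.187124,0.588631
8.57894,41.0223,40.2849,40.2819,0.18681,0.553645
9.05482,35.0355,34.3322,34.329,0.186481,0.520014
9.55711,29.9298,29.2593,29.2559,0.186135,0.48777
10.0872,25.5613,24.9221,24.9186,0.185772,0.456935
10.6468,21.7754,21.1662,21.1625,0.18539,0.427516
11.2374,18.5571,17.9765,17.9726,0.18499,0.399513
11.8607,15.8211,15.2677,15.2636,0.18457,0.372914
12.5187,13.4947,12.9671,12.9629,0.184129,0.347699
13.2131,11.5164,11.0134,11.0089,0.183667,0.323841
13.946,9.83401,9.35424,9.34952,0.183183,0.301308
14.7196,8.40298,7.94519,7.94025,0.182675,0.280059
15.5362,7.16974,6.73274,6.72754,0.182144,0.260054
16.398,6.11569,5.6983,5.69286,0.181587,0.241246
17.3076,5.2219,4.82301,4.81731,0.181004,0.223588
18.2677,4.46384,4.08239,4.07641,0.180394,0.20703
19.281,3.82075,3.45573,3.44947,0.179757,0.191524
20.3505,3.27188,2.92233,2.91577,0.17909,0.17702
21.4794,2.80086,2.46587,2.459,0.178394,0.163467
22.6709,2.40227,2.08097,2.07379,0.177667,0.150818
23.9285,2.06485,1.75643,1.74892,0.176908,0.139025
25.2558,1.7791,1.4828,1.47494,0.176116,0.128041
26.6568,1.537,1.25209,1.24388,0.17529,0.117823
28.1354,1.33178,1.0576,1.04902,0.17443,0.108326
29.6962,1.15773,0.893639,0.88469,0.173535,0.0995084
31.3434,1.00792,0.753327,0.74399,0.172603,0.0913313
33.0821,0.880644,0.634991,0.625255,0.171634,0.0837558
34.9172,0.772841,0.535616,0.525469,0.170627,0.0767454
36.8541,0.681455,0.452178,0.441608,0.169582,0.070265
38.8984,0.603909,0.382134,0.371131,0.168497,0.0642811
41.0562,0.537539,0.322851,0.311405,0.167372,0.0587617
43.3336,0.480728,0.272745,0.260845,0.166207,0.0536764
45.7374,0.432491,0.230857,0.218494,0.165001,0.0489961
48.2745,0.391466,0.195855,0.183019,0.163754,0.0446933
50.9523,0.356361,0.166472,0.153154,0.162465,0.0407416
53.7787,0.326182,0.141738,0.12793,0.161135,0.0371162
56.7619,0.300418,0.121166,0.106861,0.159764,0.0337936
59.9105,0.278363,0.10407,0.0892611,0.15835,0.0307516
63.2338,0.259124,0.0895769,0.0742591,0.156896,0.0279691
66.7415,0.242598,0.0776034,0.0617714,0.155401,0.0254265
70.4437,0.228354,0.0677336,0.0513837,0.153865,0.0231053
74.3513,0.21602,0.0596135,0.0427428,0.152289,0.020988
78.4756,0.205288,0.0529483,0.035555,0.150674,0.0190585
82.8288,0.195762,0.0473556,0.0294391,0.149021,0.0173017
87.4234,0.187347,0.0427519,0.0243127,0.147331,0.0157034
92.2729,0.179935,0.0390392,0.020079,0.145605,0.0142506
97.3913,0.173358,0.0360607,0.0165826,0.143844,0.012931
102.794,0.167345,0.0335526,0.0135606,0.142051,0.0117335
108.496,0.161857,0.0314853,0.0109849,0.140225,0.0106475
114.514,0.156932,0.0299007,0.00889841,0.13837,0.0096634
120.866,0.152467,0.0287044,0.00720825,0.136486,0.0087724
127.571,0.148382,0.02782,0.00583912,0.134577,0.00796626
134.648,0.14461,0.0271854,0.00473003,0.132643,0.00723745
142.117,0.141098,0.0267501,0.00383161,0.130687,0.00657907
150,0.1378,0.0264728,0.00310384,0.128711,0.00598477
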