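energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,730.4,722.613,722.611,0.155521,7.63306
5.27736,639.794,632.244,632.242,0.155358,7.39669
5.5701,560.489,553.176,553.175,0.155186,7.15926
5.87908,491.071,483.997,483.995,0.155005,6.92107
6.2052,429.677,422.841,422.839,0.154814,6.68244
6.54941,375.678,369.082,369.08,0.154614,6.44368
6.91271,328.515,322.157,322.155,0.154403,6.2051
7.29616,287.318,281.198,281.196,0.154181,5.96706
7.70089,251.329,245.447,245.445,0.153948,5.72991
8.12807,219.734,214.088,214.086,0.153703,5.49405
8.57894,191.827,186.416,186.413,0.153446,5.2599
9.05482,167.499,162.32,162.317,0.153175,5.02792
9.55711,146.288,141.339,141.336,0.152891,4.79858
10.0872,127.486,122.764,122.761,0.152593,4.57239
10.6468,109.752,105.253,105.25,0.15228,4.34986
11.2374,94.5197,90.2395,90.2363,0.151951,4.13149
11.8607,81.434,77.3679,77.3646,0.151606,3.9178
12.5187,70.1894,66.3325,66.3289,0.151244,3.70926
13.0287,62.9019,59.196,59.1923,0.150965,3.55859
13.0417,162.098,158.396,158.392,0.150958,3.55486
13.2131,156.541,152.888,152.884,0.150864,3.50632
13.946,135.527,132.071,132.067,0.150467,3.30942
14.7196,117.354,114.089,114.085,0.15005,3.11889
15.1924,108.302,105.146,105.141,0.149796,3.01042
15.2076,148.498,145.346,145.341,0.149788,3.00703
15.5362,141.071,137.99,137.986,0.149613,2.93507
15.8529,134.402,131.389,131.385,0.149444,2.86813
15.8687,154.798,151.788,151.784,0.149436,2.86483
16.398,142.488,139.585,139.581,0.149156,2.75819
17.3076,124.335,121.602,121.598,0.148677,2.58844
18.2677,108.506,105.936,105.931,0.148176,2.42596
19.281,94.702,92.2887,92.2836,0.147652,2.27081
20.3505,82.5566,80.2918,80.2864,0.147105,2.123
21.4794,71.7812,69.6578,69.6521,0.146533,1.98249
22.6709,62.4215,60.4323,60.4264,0.145935,1.8492
23.9285,54.291,52.4288,52.4227,0.145312,1.723
25.2558,47.2274,45.4855,45.479,0.144662,1.60372
26.6568,41.0903,39.4619,39.4551,0.143984,1.49118
28.1354,35.7576,34.2362,34.2291,0.143277,1.38516
29.6962,31.1233,29.7027,29.6953,0.142542,1.28543
31.3434,27.0449,25.7191,25.7114,0.141776,1.19176
33.0821,23.4966,22.2598,22.2518,0.14098,1.10389
34.9172,20.4194,19.266,19.2576,0.140153,1.02155
36.8541,17.7502,16.6751,16.6664,0.139294,0.944504
38.8984,15.4347,14.4329,14.4238,0.138403,0.872482
41.0562,13.4149,12.4815,12.4721,0.137479,0.805235
43.3336,11.6535,10.7842,10.7745,0.136522,0.742513
45.7374,10.1275,9.31801,9.30785,0.135532,0.684075
48.2745,8.80508,8.05143,8.04088,0.134507,0.629684
50.9523,7.65628,6.95466,6.94372,0.133449,0.579114
53.7787,6.65649,6.00333,5.99199,0.132357,0.532146
56.7619,5.79051,5.18246,5.17071,0.13123,0.488571
59.9105,5.04026,4.47416,4.462,0.130069,0.448185
63.2338,4.38709,3.86,3.84742,0.128874,0.410797
66.7415,3.82129,3.33043,3.31742,0.127646,0.376221
70.4437,3.3311,2.87386,2.86043,0.126384,0.344282
74.3513,2.90629,2.48025,2.46639,0.12509,0.314809
78.4756,2.53804,2.14092,2.12663,0.123764,0.287644
82.8288,2.21764,1.84732,1.8326,0.122406,0.262632
87.4234,1.93935,1.59385,1.5787,0.121018,0.239628
87.9605,1.91022,1.56742,1.55223,0.120858,0.237138
88.0485,7.68275,7.34039,7.32519,0.120832,0.236734
92.2729,6.81395,6.49143,6.47585,0.1196,0.218493
97.3913,5.93594,5.63469,5.61869,0.118154,0.199095
102.794,5.17498,4.89341,4.87699,0.11668,0.181311
108.496,4.51506,4.25169,4.23486,0.115181,0.165023
114.514,3.94105,3.69452,3.67727,0.113657,0.150119
120.866,3.44171,3.21076,3.1931,0.11211,0.136495
127.571,3.00727,2.79073,2.77268,0.110541,0.124053
134.648,2.62927,2.42606,2.40761,0.108953,0.112701
142.117,2.30031,2.10944,2.09061,0.107346,0.102352
150,2.014,1.83455,1.81535,0.105724,0.0929256
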