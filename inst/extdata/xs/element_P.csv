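energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,292.053,290.712,290.711,0.190309,1.15199
5.27736,250.521,249.232,249.23,0.190109,1.10034
5.5701,214.908,213.671,213.669,0.189898,1.04933
5.87908,184.37,183.183,183.181,0.189677,0.999085
6.2052,157.992,156.856,156.853,0.189444,0.949712
6.54941,135.301,134.213,134.211,0.189199,0.901328
6.91271,115.88,114.839,114.837,0.188941,0.854044
7.29616,99.2563,98.2623,98.2597,0.188669,0.807964
7.70089,85.0271,84.0782,84.0755,0.188384,0.763186
8.12807,72.804,71.899,71.8961,0.188085,0.719797
8.57894,62.2592,61.3966,61.3935,0.18777,0.677873
9.05482,53.2501,52.4284,52.4252,0.187439,0.637478
9.55711,45.5526,44.7703,44.7669,0.187091,0.598659
10.0872,38.9613,38.2166,38.2131,0.186726,0.561454
10.6468,33.2676,32.5591,32.5554,0.186343,0.525883
11.2374,28.4132,27.7392,27.7353,0.18594,0.491955
11.8607,24.2741,23.633,23.6289,0.185518,0.459668
12.5187,20.7445,20.1348,20.1305,0.185075,0.429008
13.2131,17.7346,17.1545,17.15,0.184611,0.399949
13.946,15.1674,14.6156,14.6108,0.184124,0.372461
14.7196,12.9777,12.4526,12.4476,0.183614,0.346503
15.5362,11.0833,10.5834,10.5782,0.183079,0.32203
16.398,9.45896,8.98292,8.97745,0.18252,0.298993
17.3076,8.07822,7.62469,7.61895,0.181934,0.277338
18.2677,6.90436,6.47204,6.46603,0.181321,0.25701
19.281,5.9062,5.49387,5.48757,0.18068,0.237952
20.3505,5.05193,4.65841,4.65182,0.18001,0.220107
21.4794,4.31652,3.94069,3.93379,0.17931,0.203417
22.6709,3.693,3.33381,3.32659,0.178579,0.187824
23.9285,3.16421,2.82067,2.81312,0.177816,0.173272
25.2558,2.71563,2.3868,2.3789,0.17702,0.159707
26.6568,2.33497,2.01996,2.01171,0.176191,0.147074
28.1354,2.01184,1.70981,1.70119,0.175326,0.135323
29.6962,1.73744,1.4476,1.43861,0.174426,0.124402
31.3434,1.50087,1.2225,1.21311,0.173489,0.114265
33.0821,1.29967,1.03207,1.02229,0.172515,0.104865
34.9172,1.12914,0.871678,0.861479,0.171503,0.0961579
36.8541,0.98452,0.736591,0.725967,0.170452,0.0881011
38.8984,0.861788,0.62283,0.611771,0.169362,0.0806543
41.0562,0.756808,0.526302,0.514797,0.168232,0.073779
43.3336,0.667026,0.444488,0.432527,0.16706,0.0674382
45.7374,0.59085,0.375832,0.363405,0.165848,0.0615968
48.2745,0.526145,0.318232,0.305329,0.164595,0.0562213
50.9523,0.47089,0.269697,0.256311,0.1633,0.0512799
53.7787,0.423518,0.228692,0.214813,0.161963,0.0467424
56.7619,0.383198,0.194412,0.180033,0.160584,0.04258
59.9105,0.348815,0.16577,0.150885,0.159164,0.0387658
63.2338,0.318999,0.141419,0.126023,0.157702,0.035274
66.7415,0.293526,0.12116,0.105247,0.156199,0.0320805
70.4437,0.271714,0.10433,0.0878965,0.154655,0.0291626
74.3513,0.252976,0.0903635,0.0734061,0.153071,0.0264991
78.4756,0.236823,0.0787872,0.0613046,0.151448,0.0240699
82.8288,0.222639,0.0690042,0.0509957,0.149787,0.0218563
87.4234,0.210256,0.0608613,0.0423274,0.148088,0.019841
92.2729,0.199493,0.0541901,0.0351326,0.146353,0.0180078
97.3913,0.190085,0.0487389,0.0291607,0.144583,0.0163415
102.794,0.181611,0.0440976,0.0240029,0.14278,0.0148283
108.496,0.174,0.0402058,0.0196,0.140945,0.013455
114.514,0.167295,0.0371149,0.0160048,0.13908,0.0122098
120.866,0.161338,0.0346755,0.013069,0.137187,0.0110816
127.571,0.156,0.0327655,0.0106717,0.135268,0.0100602
134.648,0.151174,0.0312849,0.00871418,0.133324,0.00913616
142.117,0.146775,0.0301519,0.00711572,0.131358,0.00830082
150,0.142729,0.0292994,0.00581047,0.129372,0.00754627
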