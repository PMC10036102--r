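energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,189.9,187.232,187.231,0.179339,2.48999
5.27736,164.913,162.343,162.341,0.179151,2.39304
5.5701,143.236,140.762,140.761,0.178952,2.29652
5.87908,124.428,122.051,122.049,0.178743,2.20061
6.2052,107.324,105.042,105.04,0.178524,2.10546
6.54941,92.1844,89.9971,89.9949,0.178293,2.01128
6.91271,79.2012,77.1072,77.1049,0.17805,1.91827
7.29616,68.0656,66.0636,66.0612,0.177794,1.82662
7.70089,58.5133,56.6018,56.5992,0.177525,1.73655
8.12807,50.3394,48.5166,48.5139,0.177243,1.64826
8.57894,43.3664,41.6304,41.6275,0.176946,1.56197
8.97451,38.3008,36.6355,36.6325,0.176687,1.49158
8.98349,282.967,281.304,281.301,0.176681,1.49003
9.05482,277.403,275.751,275.748,0.176634,1.47786
9.55711,242.054,240.485,240.482,0.176307,1.3961
10.0872,210.999,209.509,209.506,0.175963,1.31687
10.6468,182.943,181.53,181.527,0.175601,1.2403
11.2374,158.626,157.288,157.284,0.175222,1.1665
11.8607,137.55,136.283,136.28,0.174824,1.09557
12.5187,119.282,118.084,118.08,0.174407,1.02758
13.2131,103.447,102.315,102.31,0.173969,0.962564
13.946,89.7212,88.6517,88.6472,0.17351,0.900542
14.7196,77.8231,76.8133,76.8086,0.17303,0.841509
15.5362,67.2733,66.3202,66.3153,0.172526,0.785441
16.398,58.0509,57.1517,57.1466,0.171999,0.732296
17.3076,50.099,49.2509,49.2455,0.171447,0.682016
18.2677,43.2422,42.4425,42.4368,0.170869,0.634529
19.281,37.3296,36.5755,36.5695,0.170265,0.589755
20.3505,32.1837,31.4727,31.4665,0.169634,0.547602
21.4794,27.6675,26.9971,26.9906,0.168974,0.507976
22.6709,23.7904,23.1581,23.1513,0.168285,0.470774
23.9285,20.4617,19.8653,19.8582,0.167566,0.435893
25.2558,17.6035,17.0409,17.0335,0.166816,0.403229
26.6568,15.1493,14.6184,14.6106,0.166035,0.372676
28.1354,13.0417,12.5404,12.5323,0.16522,0.34413
29.6962,11.2315,10.7582,10.7497,0.164372,0.317489
31.3434,9.64355,9.19625,9.18741,0.163489,0.292651
33.0821,8.2777,7.85484,7.84561,0.162571,0.269519
34.9172,7.1094,6.70939,6.69978,0.161618,0.248
36.8541,6.10993,5.73131,5.7213,0.160627,0.228
38.8984,5.25475,4.89614,4.88572,0.1596,0.209434
41.0562,4.51761,4.17771,4.16686,0.158534,0.192216
43.3336,3.88263,3.5602,3.54893,0.157431,0.176266
45.7374,3.34043,3.03435,3.02264,0.156288,0.161506
48.2745,2.87736,2.58655,2.57439,0.155107,0.147863
50.9523,2.48035,2.20381,2.19119,0.153887,0.135266
53.7787,2.13906,1.87586,1.86278,0.152627,0.123648
56.7619,1.84786,1.59714,1.58359,0.151328,0.112943
59.9105,1.59933,1.36027,1.34625,0.149989,0.103092
63.2338,1.38494,1.1568,1.14229,0.148611,0.0940353
66.7415,1.2021,0.984179,0.969183,0.147195,0.0857184
70.4437,1.04614,0.837794,0.822308,0.14574,0.0780886
74.3513,0.913035,0.71367,0.697691,0.144248,0.0710964
78.4756,0.799372,0.608434,0.591959,0.142718,0.0646948
82.8288,0.701636,0.518615,0.501644,0.141153,0.0588398
87.4234,0.617866,0.44229,0.424825,0.139552,0.0534897
92.2729,0.546291,0.377728,0.359769,0.137917,0.0486056
97.3913,0.485076,0.323125,0.304676,0.136249,0.0441509
102.794,0.43241,0.276705,0.257768,0.13455,0.0400915
108.496,0.387095,0.237297,0.217879,0.132821,0.0363954
114.514,0.348259,0.204056,0.184163,0.131063,0.033033
120.866,0.31492,0.176025,0.155664,0.129279,0.0299767
127.571,0.286247,0.152396,0.131575,0.127471,0.0272009
134.648,0.261535,0.132484,0.111214,0.125639,0.0246818
142.117,0.240188,0.115712,0.0940042,0.123786,0.0223975
150,0.2217,0.101592,0.0794572,0.121915,0.0203276
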