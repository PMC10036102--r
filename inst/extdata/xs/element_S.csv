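energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,351.794,350.311,350.309,0.19612,1.28911
5.27736,301.755,300.329,300.327,0.195914,1.23208
5.5701,258.848,257.479,257.477,0.195697,1.17571
5.87908,222.056,220.743,220.74,0.195468,1.12013
6.2052,190.328,189.07,189.067,0.195228,1.06546
6.54941,163.054,161.849,161.847,0.194976,1.01183
6.91271,139.699,138.548,138.545,0.19471,0.959356
7.29616,119.701,118.601,118.599,0.19443,0.908162
7.70089,102.576,101.526,101.524,0.194137,0.858358
8.12807,87.8707,86.8698,86.8669,0.193828,0.810044
8.57894,75.2008,74.2472,74.244,0.193503,0.763309
9.05482,64.3668,63.4587,63.4554,0.193162,0.718228
9.55711,55.1022,54.238,54.2346,0.192804,0.674861
10.0872,47.1659,46.3439,46.3402,0.192427,0.633253
10.6468,40.3207,39.5391,39.5352,0.192032,0.593434
11.2374,34.4766,33.7336,33.7296,0.191618,0.55542
11.8607,29.4869,28.7807,28.7765,0.191183,0.519211
12.5187,25.2262,24.5551,24.5507,0.190726,0.484798
13.2131,21.5879,20.9501,20.9455,0.190248,0.452158
13.946,18.4807,17.8746,17.8697,0.189746,0.421259
14.7196,15.8268,15.2507,15.2455,0.18922,0.39206
15.5362,13.5266,12.9788,12.9735,0.188669,0.364514
16.398,11.5515,11.0304,11.0248,0.188093,0.338569
17.3076,9.87048,9.37474,9.36883,0.187489,0.314167
18.2677,8.4397,7.96779,7.96159,0.186857,0.291248
19.281,7.22168,6.77222,6.76573,0.186197,0.26975
20.3505,6.17783,5.7495,5.74271,0.185506,0.249611
21.4794,5.27782,4.86938,4.86227,0.184785,0.230766
22.6709,4.514,4.12425,4.11681,0.184032,0.213152
23.9285,3.8656,3.49343,3.48564,0.183246,0.196708
25.2558,3.31504,2.95938,2.95124,0.182425,0.181371
26.6568,2.84743,2.50728,2.49878,0.18157,0.167083
28.1354,2.45014,2.12456,2.11568,0.18068,0.153787
29.6962,2.11249,1.80058,1.79131,0.179752,0.141425
31.3434,1.82112,1.52206,1.51239,0.178787,0.129945
33.0821,1.57313,1.28614,1.27605,0.177783,0.119295
34.9172,1.36281,1.08716,1.07665,0.17674,0.109426
36.8541,1.18435,0.919351,0.908403,0.175657,0.10029
38.8984,1.03283,0.777847,0.76645,0.174533,0.0918424
41.0562,0.903202,0.657651,0.645795,0.173368,0.0840395
43.3336,0.792336,0.555661,0.543335,0.172162,0.07684
45.7374,0.698248,0.469937,0.457131,0.170912,0.0702047
48.2745,0.61832,0.3979,0.384604,0.169621,0.064096
50.9523,0.550081,0.337112,0.323316,0.168286,0.0584782
53.7787,0.491603,0.28568,0.271378,0.166908,0.0533173
56.7619,0.441851,0.2426,0.227783,0.165487,0.0485813
59.9105,0.399454,0.20653,0.191191,0.164024,0.0442395
63.2338,0.362752,0.175839,0.159972,0.162517,0.0402632
66.7415,0.331432,0.150238,0.133839,0.160968,0.0366252
70.4437,0.304652,0.128911,0.111975,0.159377,0.0333
74.3513,0.281691,0.111158,0.0936825,0.157745,0.0302634
78.4756,0.261944,0.0963949,0.0783784,0.156072,0.027493
82.8288,0.244663,0.0838935,0.0653351,0.15436,0.0249677
87.4234,0.22963,0.073452,0.0543522,0.15261,0.0226678
92.2729,0.216612,0.064855,0.0452156,0.150822,0.0205749
97.3913,0.205285,0.0577908,0.0376148,0.148998,0.0186721
102.794,0.195136,0.0517615,0.0310532,0.14714,0.0169434
108.496,0.186072,0.0466837,0.0254487,0.145249,0.0153742
114.514,0.178134,0.0426104,0.0208558,0.143327,0.0139509
120.866,0.171129,0.039358,0.0170917,0.141376,0.0126609
127.571,0.164898,0.0367754,0.014007,0.139398,0.0114926
134.648,0.159309,0.0347389,0.011479,0.137395,0.0104354
142.117,0.154256,0.0331468,0.0094073,0.135369,0.00947935
150,0.149648,0.0319156,0.00770947,0.133323,0.00861553
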