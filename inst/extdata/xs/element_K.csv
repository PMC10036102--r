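energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,577.335,575.585,575.583,0.19097,1.56126
5.27736,495.156,493.473,493.471,0.190769,1.49466
5.5701,424.692,423.075,423.073,0.190558,1.42868
5.87908,364.271,362.72,362.718,0.190335,1.36345
6.2052,312.395,310.908,310.905,0.190101,1.29912
6.54941,267.885,266.462,266.459,0.189855,1.23584
6.91271,229.731,228.37,228.367,0.189597,1.17374
7.29616,197.023,195.723,195.721,0.189324,1.11298
7.70089,168.984,167.744,167.741,0.189038,1.05369
8.12807,144.931,143.749,143.746,0.188738,0.996
8.57894,124.281,123.155,123.152,0.188421,0.940026
9.05482,106.583,105.512,105.509,0.188089,0.885871
9.55711,91.4144,90.3964,90.393,0.18774,0.833624
10.0872,78.4084,77.4413,77.4377,0.187374,0.783356
10.6468,67.2383,66.3199,66.3162,0.186989,0.735118
11.2374,57.6674,56.7958,56.7919,0.186586,0.688948
11.8607,49.4665,48.6396,48.6355,0.186162,0.644864
12.5187,42.4391,41.6548,41.6505,0.185718,0.602869
13.2131,36.4169,35.6732,35.6687,0.185252,0.56295
13.946,31.2558,30.5507,30.546,0.184763,0.525084
14.7196,26.8324,26.164,26.159,0.184251,0.489233
15.5362,22.9798,22.346,22.3408,0.183715,0.455351
16.398,19.6583,19.0573,19.0518,0.183153,0.423385
17.3076,16.8229,16.2528,16.247,0.182565,0.393272
18.2677,14.4021,13.8612,13.8552,0.18195,0.364949
19.281,12.3351,11.8218,11.8155,0.181307,0.338345
20.3505,10.5574,10.07,10.0634,0.180635,0.313388
21.4794,9.01837,8.55536,8.54843,0.179932,0.290007
22.6709,7.70887,7.26879,7.26155,0.179199,0.268127
23.9285,6.5945,6.17597,6.16839,0.178433,0.247675
25.2558,5.64602,5.24773,5.2398,0.177635,0.22858
26.6568,4.83857,4.45928,4.451,0.176802,0.21077
28.1354,4.15106,3.78959,3.78095,0.175935,0.194176
29.6962,3.56553,3.22079,3.21176,0.175032,0.178733
31.3434,3.059,2.72995,2.72054,0.174092,0.164375
33.0821,2.62708,2.31274,2.30292,0.173114,0.15104
34.9172,2.26018,1.95965,1.94942,0.172099,0.138668
36.8541,1.94842,1.66083,1.65017,0.171044,0.127203
38.8984,1.6834,1.40796,1.39686,0.16995,0.116589
41.0562,1.45663,1.19258,1.18104,0.168816,0.106773
43.3336,1.26264,1.0093,0.997295,0.16764,0.0977065
45.7374,1.0979,0.854607,0.842137,0.166424,0.0893404
48.2745,0.957913,0.724065,0.711118,0.165166,0.0816293
50.9523,0.838458,0.613494,0.600061,0.163867,0.0745297
53.7787,0.736212,0.519614,0.505687,0.162525,0.0680003
56.7619,0.649299,0.440584,0.426155,0.161142,0.0620015
59.9105,0.575345,0.374068,0.359132,0.159716,0.0564962
63.2338,0.511618,0.31737,0.30192,0.158249,0.0514489
66.7415,0.457371,0.269773,0.253804,0.156741,0.0468261
70.4437,0.411145,0.229848,0.213357,0.155192,0.0425965
74.3513,0.371688,0.196371,0.179355,0.153603,0.0387302
78.4756,0.337945,0.168316,0.150772,0.151974,0.0351993
82.8288,0.308669,0.144455,0.126384,0.150307,0.0319778
87.4234,0.283417,0.124373,0.105774,0.148602,0.0290411
92.2729,0.261753,0.107649,0.0885254,0.146861,0.0263664
97.3913,0.243107,0.0937354,0.0740892,0.145085,0.0239324
102.794,0.226642,0.0818117,0.0616473,0.143276,0.0217192
108.496,0.212152,0.0716863,0.051009,0.141435,0.0197085
114.514,0.199653,0.06339,0.0422066,0.139563,0.0178832
120.866,0.188814,0.0566047,0.0349231,0.137663,0.0162275
127.571,0.179361,0.0510671,0.0288966,0.135737,0.0147268
134.648,0.171065,0.0465591,0.02391,0.133787,0.0133677
142.117,0.163736,0.0429001,0.0197839,0.131814,0.0121377
150,0.157217,0.0399404,0.0163699,0.129822,0.0110255
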