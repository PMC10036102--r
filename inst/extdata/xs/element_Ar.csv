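energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,493.861,492.334,492.332,0.177069,1.35185
5.27736,423.564,422.095,422.094,0.176883,1.29351
5.5701,363.288,361.877,361.876,0.176687,1.23576
5.87908,311.604,310.25,310.248,0.176481,1.17871
6.2052,267.167,265.871,265.869,0.176264,1.12249
6.54941,229.019,227.778,227.776,0.176036,1.06724
6.91271,196.33,195.143,195.141,0.175796,1.01307
7.29616,168.317,167.184,167.182,0.175544,0.960118
7.70089,144.312,143.231,143.229,0.175278,0.908494
8.12807,123.714,122.683,122.681,0.174999,0.85831
8.57894,106.01,105.028,105.026,0.174706,0.809666
9.05482,90.8484,89.9144,89.9114,0.174398,0.762648
9.55711,77.8636,76.9754,76.9722,0.174075,0.717328
10.0872,66.7337,65.8895,65.8862,0.173735,0.673762
10.6468,57.162,56.3601,56.3566,0.173379,0.631994
11.2374,48.9705,48.2091,48.2054,0.173004,0.592048
11.8607,41.9597,41.237,41.2332,0.172611,0.553937
12.5187,35.9592,35.2733,35.2693,0.172199,0.517658
13.2131,30.8231,30.1723,30.1681,0.171767,0.483198
13.946,26.4265,25.8091,25.8047,0.171314,0.450531
14.7196,22.6629,22.077,22.0724,0.17084,0.419621
15.5362,19.3901,18.8342,18.8293,0.170342,0.390427
16.398,16.5723,16.0447,16.0396,0.169822,0.362897
17.3076,14.1695,13.6685,13.6632,0.169277,0.336977
18.2677,12.1202,11.6445,11.6389,0.168706,0.312609
19.281,10.3723,9.92035,9.91449,0.16811,0.28973
20.3505,8.87094,8.44131,8.43517,0.167487,0.268277
21.4794,7.57299,7.16439,7.15797,0.166835,0.248185
22.6709,6.4697,6.08087,6.07415,0.166155,0.229392
23.9285,5.53172,5.16147,5.15444,0.165445,0.211831
25.2558,4.73413,4.38133,4.37399,0.164705,0.195441
26.6568,4.0558,3.71938,3.7117,0.163933,0.18016
28.1354,3.47876,3.15772,3.1497,0.163129,0.165928
29.6962,2.98777,2.68116,2.67279,0.162291,0.152687
31.3434,2.56347,2.2704,2.26167,0.16142,0.140381
33.0821,2.202,1.92163,1.91253,0.160513,0.128956
34.9172,1.89521,1.62677,1.61728,0.159572,0.118359
36.8541,1.63475,1.3775,1.36762,0.158594,0.108543
38.8984,1.41353,1.16678,1.15649,0.157579,0.0994587
41.0562,1.22433,0.987449,0.976745,0.156528,0.091061
43.3336,1.06258,0.834966,0.823837,0.155438,0.0833067
45.7374,0.925331,0.706429,0.694866,0.15431,0.0761543
48.2745,0.808794,0.598091,0.586086,0.153144,0.0695643
50.9523,0.709406,0.506424,0.493969,0.151939,0.0634991
53.7787,0.624373,0.428669,0.415756,0.150695,0.0579229
56.7619,0.552141,0.363305,0.349927,0.149412,0.0528018
59.9105,0.490715,0.30837,0.294521,0.148091,0.0481035
63.2338,0.43776,0.261558,0.247232,0.14673,0.0437976
66.7415,0.392708,0.222327,0.207521,0.145332,0.0398552
70.4437,0.354332,0.189478,0.174188,0.143895,0.0362492
74.3513,0.321585,0.161987,0.146209,0.142422,0.032954
78.4756,0.293582,0.138991,0.122724,0.140912,0.0299457
82.8288,0.26926,0.119449,0.102693,0.139366,0.0272017
87.4234,0.24827,0.103028,0.0857836,0.137785,0.024701
92.2729,0.230254,0.0893903,0.0716586,0.136171,0.0224241
97.3913,0.214737,0.0780756,0.0598594,0.134524,0.0203527
102.794,0.201001,0.0683809,0.0496842,0.132847,0.0184697
108.496,0.188885,0.0601585,0.0409863,0.13114,0.0167595
114.514,0.178423,0.0534525,0.033811,0.129404,0.0152074
120.866,0.169335,0.0479953,0.0278919,0.127643,0.0137998
127.571,0.161391,0.0435658,0.023009,0.125857,0.0125244
134.648,0.154399,0.0399815,0.018981,0.124049,0.0113696
142.117,0.148202,0.0370916,0.0156581,0.12222,0.0103247
150,0.142669,0.0347717,0.0129169,0.120372,0.00938011
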