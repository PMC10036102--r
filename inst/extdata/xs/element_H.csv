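energy_keV,mu_total,mu_en,mu_photo,mu_incoh,mu_coh
5,0.513133,0.0672723,0.0635379,0.389856,0.0597384
5.27736,0.498909,0.0576863,0.0537536,0.389446,0.0557091
5.5701,0.486387,0.0496172,0.0454759,0.389015,0.0518955
5.87908,0.475327,0.0428332,0.038473,0.388561,0.0482926
6.2052,0.46557,0.0371816,0.0325915,0.388084,0.0448943
6.54941,0.456907,0.0324627,0.0276311,0.387582,0.041694
6.91271,0.449164,0.0285107,0.0234258,0.387053,0.0386845
7.29616,0.442217,0.0252111,0.0198604,0.386498,0.0358584
7.70089,0.435959,0.0224672,0.0168377,0.385914,0.033208
8.12807,0.430298,0.0201951,0.0142733,0.3853,0.0307254
8.57894,0.425153,0.018324,0.0120958,0.384654,0.0284026
9.05482,0.420459,0.0167997,0.0102504,0.383976,0.026232
9.55711,0.416157,0.0155721,0.00868664,0.383264,0.0242057
10.0872,0.412185,0.0145903,0.00735285,0.382516,0.0223161
10.6468,0.408473,0.0137919,0.00618618,0.381731,0.020556
11.2374,0.40503,0.0131956,0.00520462,0.380907,0.0189181
11.8607,0.401816,0.0127725,0.00437881,0.380042,0.0173957
12.5187,0.398801,0.0124986,0.00368402,0.379135,0.015982
13.2131,0.395953,0.0123536,0.00309948,0.378183,0.0146707
13.946,0.393249,0.0123205,0.00260769,0.377186,0.0134557
14.7196,0.390666,0.0123854,0.00219393,0.376141,0.0123311
15.5362,0.388178,0.0125314,0.00184106,0.375046,0.0112913
16.398,0.385773,0.012753,0.0015428,0.373899,0.010331
17.3076,0.383437,0.0130443,0.00129286,0.372699,0.00944514
18.2677,0.381156,0.013398,0.00108341,0.371444,0.00862878
19.281,0.378916,0.013808,0.000907898,0.370131,0.0078773
20.3505,0.376704,0.0142678,0.000759512,0.368759,0.0071863
21.4794,0.374509,0.0147727,0.000633087,0.367325,0.00655159
22.6709,0.372324,0.0153221,0.000527705,0.365827,0.00596919
23.9285,0.370139,0.0159128,0.000439866,0.364264,0.00543534
25.2558,0.367947,0.016542,0.000366647,0.362634,0.00494649
26.6568,0.365739,0.0172075,0.000305616,0.360934,0.00449929
28.1354,0.363509,0.0179073,0.000254745,0.359163,0.00409057
29.6962,0.361249,0.0186396,0.000212341,0.35732,0.00371738
31.3434,0.358954,0.0194018,0.000175844,0.355401,0.00337693
33.0821,0.356618,0.0201939,0.000145399,0.353406,0.00306664
34.9172,0.354237,0.0210147,0.000120225,0.351332,0.00278406
36.8541,0.351806,0.0218629,9.94102e-05,0.34918,0.00252696
38.8984,0.349321,0.0227372,8.21988e-05,0.346946,0.00229322
41.0562,0.346779,0.0236361,6.76505e-05,0.34463,0.00208089
43.3336,0.344174,0.0245583,5.5399e-05,0.342231,0.00188817
45.7374,0.341507,0.025503,4.53663e-05,0.339748,0.00171339
48.2745,0.338772,0.0264685,3.71505e-05,0.33718,0.00155498
50.9523,0.335969,0.0274534,3.03042e-05,0.334527,0.00141154
53.7787,0.333094,0.0284559,2.45409e-05,0.331788,0.00128175
56.7619,0.330148,0.0294746,1.98737e-05,0.328964,0.00116439
59.9105,0.327128,0.0305078,1.60941e-05,0.326054,0.00105836
63.2338,0.324034,0.0315531,1.26613e-05,0.323059,0.000962638
66.7415,0.320866,0.032609,9.95254e-06,0.31998,0.000876288
70.4437,0.317624,0.0336734,7.82329e-06,0.316818,0.000798455
74.3513,0.314308,0.0347441,6.14957e-06,0.313573,0.000728359
78.4756,0.310918,0.0358188,4.83393e-06,0.310248,0.000665284
82.8288,0.307457,0.0368949,3.59128e-06,0.306845,0.000608579
87.4234,0.303925,0.0379701,2.58601e-06,0.303365,0.000557648
92.2729,0.300324,0.0390421,1.86214e-06,0.299811,0.000511949
97.3913,0.296657,0.0401082,1.34089e-06,0.296185,0.000470988
102.794,0.292926,0.0411653,4.52066e-07,0.292491,0.000434315
108.496,0.289134,0.0422119,7.35951e-08,0.288733,0.00040152
114.514,0.285285,0.043245,1.19811e-08,0.284912,0.000372228
120.866,0.28138,0.044262,1.95048e-09,0.281034,0.000346098
127.571,0.277425,0.0452602,3.17532e-10,0.277102,0.000322821
134.648,0.273423,0.0462372,5.16933e-11,0.27312,0.000302114
142.117,0.269377,0.0471906,8.41552e-12,0.269093,0.000283717
150,0.265293,0.0481182,1.37002e-12,0.265025,0.000267397
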