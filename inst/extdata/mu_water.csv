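# linear attenuation coefficient, computed from Cromer-Liberman + Klein-Nishina + IT92 form factors
# material: water, density 1.0 g/cm3
energy_keV,mu_per_cm
5,40.8277
6,23.6808
7,14.9277
8,10.0147
9,7.05391
10,5.16829
11,3.90822
12,3.04108
13,2.42536
14,1.9763
15,1.64117
16,1.38599
17,1.18825
18,1.0326
19,0.908356
20,0.807937
21,0.725848
22,0.65805
23,0.601528
24,0.554001
25,0.51372
26,0.47933
27,0.449696
28,0.42393
29,0.40155
30,0.382001
31,0.364836
32,0.349688
33,0.336257
34,0.324296
35,0.313599
36,0.303994
37,0.295336
38,0.287505
39,0.280395
40,0.27392
41,0.268003
42,0.262581
43,0.257596
44,0.253001
45,0.248754
46,0.244818
47,0.241161
48,0.237755
49,0.234576
50,0.231601
51,0.228812
52,0.22619
53,0.223723
54,0.221394
55,0.219194
56,0.21711
57,0.215134
58,0.213256
59,0.211468
60,0.209765
61,0.208138
62,0.206584
63,0.205095
64,0.203668
65,0.202298
66,0.200981
67,0.199714
68,0.198493
69,0.197316
70,0.196179
71,0.19508
72,0.194016
73,0.192987
74,0.191988
75,0.19102
76,0.190079
77,0.189165
78,0.188276
79,0.187411
80,0.186567
81,0.185746
82,0.184944
83,0.184162
84,0.183397
85,0.18265
86,0.18192
87,0.181205
88,0.180506
89,0.17982
90,0.179149
91,0.17849
92,0.177844
93,0.177211
94,0.176588
95,0.175977
96,0.175377
97,0.174787
98,0.174206
99,0.173635
100,0.173074
101,0.172521
102,0.171976
103,0.17144
104,0.170912
105,0.170391
106,0.169878
107,0.169372
108,0.168873
109,0.16838
110,0.167894
111,0.167414
112,0.166941
113,0.166473
114,0.166011
115,0.165555
116,0.165104
117,0.164659
118,0.164219
119,0.163783
120,0.163353
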