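# linear attenuation coefficient, computed from Cromer-Liberman + Klein-Nishina + IT92 form factors
# material: adipose, density 0.95 g/cm3
energy_keV,mu_per_cm
5,23.4818
6,13.5888
7,8.56846
8,5.7647
9,4.08075
10,3.00843
11,2.29571
12,1.80564
13,1.45774
14,1.20396
15,1.01446
16,0.870037
17,0.757975
18,0.669635
19,0.599
20,0.541802
21,0.494949
22,0.456168
23,0.423763
24,0.396448
25,0.373239
26,0.353369
27,0.336199
28,0.321226
29,0.308178
30,0.296741
31,0.286661
32,0.277729
33,0.269777
34,0.262664
35,0.256273
36,0.250506
37,0.245281
38,0.240529
39,0.236192
40,0.232218
41,0.228567
42,0.225199
43,0.222085
44,0.219196
45,0.216508
46,0.214001
47,0.211655
48,0.209457
49,0.20739
50,0.205443
51,0.203605
52,0.201866
53,0.200218
54,0.198652
55,0.197162
56,0.195742
57,0.194385
58,0.193088
59,0.191846
60,0.190654
61,0.189508
62,0.188407
63,0.187346
64,0.186322
65,0.185334
66,0.184379
67,0.183455
68,0.18256
69,0.181692
70,0.18085
71,0.180032
72,0.179237
73,0.178463
74,0.17771
75,0.176976
76,0.17626
77,0.175562
78,0.17488
79,0.174214
80,0.173563
81,0.172927
82,0.172304
83,0.171695
84,0.171098
85,0.170513
86,0.169939
87,0.169377
88,0.168826
89,0.168284
90,0.167753
91,0.167231
92,0.166719
93,0.166215
94,0.16572
95,0.165233
96,0.164754
97,0.164284
98,0.16382
99,0.163364
100,0.162916
101,0.162474
102,0.162039
103,0.16161
104,0.161188
105,0.160772
106,0.160363
107,0.159959
108,0.159561
109,0.159168
110,0.158781
111,0.1584
112,0.158024
113,0.157653
114,0.157286
115,0.156925
116,0.156569
117,0.156217
118,0.155871
119,0.155528
120,0.15519
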