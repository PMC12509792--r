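# linear attenuation coefficient, computed from Cromer-Liberman + Klein-Nishina + IT92 form factors
# material: tumor, density 1.044 g/cm3
energy_keV,mu_per_cm
5,42.2259
6,24.604
7,15.5689
8,10.4785
9,7.40082
10,5.43366
11,4.11742
12,3.20921
13,2.56277
14,2.09031
15,1.73703
16,1.46753
17,1.25833
18,1.09343
19,0.961657
20,0.855032
21,0.767788
22,0.695672
23,0.635507
24,0.584884
25,0.541957
26,0.505292
27,0.473686
28,0.446199
29,0.422317
30,0.401453
31,0.383128
32,0.366955
33,0.352615
34,0.339842
35,0.32842
36,0.318164
37,0.30892
38,0.300559
39,0.29297
40,0.286059
41,0.279746
42,0.273962
43,0.268646
44,0.263749
45,0.259223
46,0.255032
47,0.251139
48,0.247517
49,0.244137
50,0.240978
51,0.238018
52,0.23524
53,0.232626
54,0.230164
55,0.227839
56,0.225641
57,0.223559
58,0.221584
59,0.219708
60,0.217923
61,0.216222
62,0.2146
63,0.21305
64,0.211568
65,0.210149
66,0.208789
67,0.207485
68,0.206232
69,0.205027
70,0.203868
71,0.202752
72,0.201677
73,0.20064
74,0.199639
75,0.198672
76,0.197738
77,0.196834
78,0.19596
79,0.195115
80,0.194295
81,0.193502
82,0.192732
83,0.191987
84,0.191263
85,0.190561
86,0.18988
87,0.189219
88,0.188577
89,0.187953
90,0.187348
91,0.186759
92,0.186188
93,0.185632
94,0.185092
95,0.184568
96,0.184058
97,0.183563
98,0.183082
99,0.182614
100,0.18216
101,0.181719
102,0.18129
103,0.180874
104,0.180469
105,0.180077
106,0.179696
107,0.179327
108,0.178968
109,0.178621
110,0.178284
111,0.177957
112,0.177641
113,0.177335
114,0.177039
115,0.176752
116,0.176475
117,0.176208
118,0.17595
119,0.175701
120,0.175461
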