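# linear attenuation coefficient, computed from Cromer-Liberman + Klein-Nishina + IT92 form factors
# material: breast, density 1.02 g/cm3
energy_keV,mu_per_cm
5,33.2978
6,19.3158
7,12.1876
8,8.19103
9,5.78379
10,4.24934
11,3.22593
12,2.52139
13,2.02087
14,1.65562
15,1.38286
16,1.17501
17,1.01381
18,0.8868
19,0.785328
20,0.703232
21,0.636054
22,0.580515
23,0.534164
24,0.495148
25,0.462044
26,0.43375
27,0.409341
28,0.388095
29,0.369617
30,0.353454
31,0.33924
32,0.326677
33,0.31552
34,0.305566
35,0.296649
36,0.288626
37,0.281381
38,0.274813
39,0.268839
40,0.263386
41,0.258392
42,0.253805
43,0.249578
44,0.245673
45,0.242055
46,0.238694
47,0.235565
48,0.232643
49,0.229909
50,0.227345
51,0.224936
52,0.222667
53,0.220526
54,0.218502
55,0.216586
56,0.214768
57,0.213041
58,0.211397
59,0.20983
60,0.208334
61,0.206905
62,0.205537
63,0.204226
64,0.202968
65,0.20176
66,0.200599
67,0.199482
68,0.198405
69,0.197367
70,0.196366
71,0.195398
72,0.194463
73,0.193559
74,0.192683
75,0.191835
76,0.191014
77,0.190217
78,0.189444
79,0.188694
80,0.187965
81,0.187258
82,0.18657
83,0.185901
84,0.185251
85,0.184618
86,0.184003
87,0.183404
88,0.182821
89,0.182253
90,0.1817
91,0.181161
92,0.180636
93,0.180125
94,0.179627
95,0.179142
96,0.178669
97,0.178208
98,0.177759
99,0.177322
100,0.176896
101,0.176481
102,0.176076
103,0.175683
104,0.175299
105,0.174926
106,0.174562
107,0.174208
108,0.173864
109,0.173529
110,0.173203
111,0.172886
112,0.172578
113,0.172278
114,0.171987
115,0.171705
116,0.171431
117,0.171165
118,0.170907
119,0.170657
120,0.170414
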