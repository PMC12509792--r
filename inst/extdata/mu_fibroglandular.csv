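# linear attenuation coefficient, computed from Cromer-Liberman + Klein-Nishina + IT92 form factors
# material: fibroglandular, density 1.04 g/cm3
energy_keV,mu_per_cm
5,38.6669
6,22.4536
7,14.1721
8,9.52167
9,6.7174
10,4.92917
11,3.7348
12,2.91217
13,2.32755
14,1.90084
15,1.58216
16,1.33933
17,1.15102
18,1.00269
19,0.884212
20,0.788387
21,0.710004
22,0.645228
23,0.591194
24,0.545733
25,0.507181
26,0.47425
27,0.44586
28,0.421165
29,0.399703
30,0.380945
31,0.364463
32,0.349909
33,0.336996
34,0.325489
35,0.31519
36,0.305937
37,0.29759
38,0.290033
39,0.283168
40,0.276911
41,0.271189
42,0.265941
43,0.261113
44,0.256659
45,0.25254
46,0.248719
47,0.245167
48,0.241857
49,0.238766
50,0.235871
51,0.233156
52,0.230604
53,0.2282
54,0.225932
55,0.223788
56,0.221758
57,0.219832
58,0.218003
59,0.216263
60,0.214605
61,0.213023
62,0.211512
63,0.210067
64,0.208683
65,0.207356
66,0.206082
67,0.204859
68,0.203682
69,0.20255
70,0.201459
71,0.200407
72,0.199392
73,0.198412
74,0.197465
75,0.196549
76,0.195664
77,0.194806
78,0.193975
79,0.19317
80,0.19239
81,0.191633
82,0.190898
83,0.190185
84,0.189493
85,0.18882
86,0.188167
87,0.187532
88,0.186915
89,0.186316
90,0.185732
91,0.185165
92,0.184613
93,0.184077
94,0.183555
95,0.183047
96,0.182554
97,0.182073
98,0.181606
99,0.181151
100,0.180709
101,0.18028
102,0.179862
103,0.179455
104,0.17906
105,0.178676
106,0.178303
107,0.177941
108,0.177589
109,0.177248
110,0.176916
111,0.176594
112,0.176283
113,0.17598
114,0.175687
115,0.175403
116,0.175128
117,0.174863
118,0.174606
119,0.174357
120,0.174117
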