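# linear attenuation coefficient, computed from Cromer-Liberman + Klein-Nishina + IT92 form factors
# material: silicon, density 2.33 g/cm3
energy_keV,mu_per_cm
5,561.418
6,336.293
7,216.973
8,147.926
9,105.223
10,77.3067
11,58.4729
12,45.3107
13,35.8382
14,28.8495
15,23.582
16,19.5377
17,16.3816
18,13.8831
19,11.8796
20,10.2545
21,8.92265
22,7.82086
23,6.90156
24,6.12852
25,5.47378
26,4.91558
27,4.4365
28,4.02275
29,3.66406
30,3.35158
31,3.07808
32,2.83767
33,2.62548
34,2.43747
35,2.2703
36,2.12113
37,1.98761
38,1.86771
39,1.75974
40,1.66223
41,1.57395
42,1.49381
43,1.42088
44,1.35437
45,1.29358
46,1.23788
47,1.18677
48,1.13975
49,1.09643
50,1.05644
51,1.01946
52,0.985205
53,0.953423
54,0.923888
55,0.896399
56,0.870778
57,0.846862
58,0.824508
59,0.803585
60,0.783976
61,0.765575
62,0.748287
63,0.732024
64,0.716708
65,0.702268
66,0.688638
67,0.675759
68,0.663576
69,0.652041
70,0.641107
71,0.630734
72,0.620883
73,0.61152
74,0.602611
75,0.594128
76,0.586043
77,0.57833
78,0.570967
79,0.563932
80,0.557204
81,0.550767
82,0.544601
83,0.538691
84,0.533024
85,0.527583
86,0.522358
87,0.517336
88,0.512505
89,0.507856
90,0.503378
91,0.499063
92,0.494902
93,0.490887
94,0.487011
95,0.483266
96,0.479646
97,0.476146
98,0.472758
99,0.469478
100,0.466301
101,0.463221
102,0.460235
103,0.457337
104,0.454525
105,0.451793
106,0.449139
107,0.446559
108,0.44405
109,0.441609
110,0.439232
111,0.436918
112,0.434663
113,0.432466
114,0.430323
115,0.428233
116,0.426194
117,0.424203
118,0.422258
119,0.420359
120,0.418503
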