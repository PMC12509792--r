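# linear attenuation coefficient, computed from Cromer-Liberman + Klein-Nishina + IT92 form factors
# material: aluminium, density 2.699 g/cm3
energy_keV,mu_per_cm
5,511.61
6,304.86
7,195.814
8,132.999
9,94.3756
10,69.2144
11,52.2777
12,40.4657
13,31.9809
14,25.7314
15,21.0283
16,17.4223
17,14.6117
18,12.3891
19,10.6088
20,9.166
21,7.98458
22,7.00797
23,6.19371
24,5.50945
25,4.93027
26,4.43676
27,4.01356
28,3.6485
29,3.33215
30,3.05663
31,2.81554
32,2.60367
33,2.4167
34,2.25107
35,2.1038
36,1.9724
37,1.85478
38,1.74917
39,1.65405
40,1.56814
41,1.49035
42,1.41971
43,1.35543
44,1.29678
45,1.24316
46,1.19402
47,1.1489
48,1.10739
49,1.06912
50,1.03377
51,1.00107
52,0.970759
53,0.942621
54,0.916457
55,0.892089
56,0.869361
57,0.84813
58,0.82827
59,0.809667
60,0.792218
61,0.775829
62,0.760417
63,0.745906
64,0.732227
65,0.719316
66,0.707118
67,0.695579
68,0.684652
69,0.674294
70,0.664465
71,0.655129
72,0.646252
73,0.637803
74,0.629755
75,0.622081
76,0.614758
77,0.607762
78,0.601075
79,0.594676
80,0.588548
81,0.582676
82,0.577044
83,0.571638
84,0.566444
85,0.561452
86,0.55665
87,0.552027
88,0.547574
89,0.543281
90,0.539139
91,0.535142
92,0.531281
93,0.52755
94,0.523941
95,0.520449
96,0.517069
97,0.513793
98,0.510619
99,0.50754
100,0.504552
101,0.501652
102,0.498834
103,0.496096
104,0.493433
105,0.490842
106,0.488321
107,0.485866
108,0.483475
109,0.481144
110,0.478871
111,0.476654
112,0.47449
113,0.472378
114,0.470315
115,0.4683
116,0.466329
117,0.464403
118,0.462519
119,0.460675
120,0.45887
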