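# linear attenuation coefficient, computed from Cromer-Liberman + Klein-Nishina + IT92 form factors
# material: tungsten, density 19.25 g/cm3
energy_keV,mu_per_cm
5,10437.7
6,6617.93
7,4490.81
8,3205.52
9,2378.65
10,1818.79
11,3690.71
12,4038.29
13,3803.25
14,3148.9
15,2639.28
16,2235.48
17,1911.66
18,1648.81
19,1433.05
20,1254.17
21,1104.46
22,978.19
23,870.918
24,779.126
25,700.122
26,631.747
27,572.16
28,519.887
29,474.004
30,433.552
31,397.738
32,365.907
33,337.513
34,312.097
35,289.275
36,268.719
37,250.15
38,233.332
39,218.06
40,204.157
41,191.473
42,179.874
43,169.245
44,159.486
45,150.496
46,142.21
47,134.561
48,127.489
49,120.941
50,114.867
51,109.217
52,103.963
53,99.0599
54,94.4826
55,90.2098
56,86.2162
57,82.4791
58,78.9778
59,75.6937
60,72.61
61,69.7112
62,66.9837
63,64.4146
64,61.9924
65,59.7066
66,57.5475
67,55.5064
68,53.5752
69,51.7463
70,212.948
71,205.782
72,198.904
73,192.29
74,185.807
75,179.632
76,173.747
77,168.135
78,162.779
79,157.665
80,152.779
81,148.127
82,143.672
83,139.405
84,135.315
85,131.394
86,127.632
87,124.021
88,120.554
89,117.224
90,114.024
91,110.929
92,107.944
93,105.073
94,102.313
95,99.6557
96,97.098
97,94.6348
98,92.2618
99,89.9747
100,87.7696
101,85.6429
102,83.591
103,81.6106
104,79.6985
105,77.8519
106,76.0678
107,74.3436
108,72.6768
109,71.065
110,69.5058
111,67.9971
112,66.5369
113,65.1231
114,63.754
115,62.4277
116,61.1426
117,59.897
118,58.6893
119,57.5183
120,56.3824
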