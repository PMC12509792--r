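# linear attenuation coefficient, computed from Cromer-Liberman + Klein-Nishina + IT92 form factors
# material: gold, density 19.32 g/cm3
energy_keV,mu_per_cm
5,12642.4
6,8047.88
7,5473.45
8,3912.89
9,2907.63
10,2226.36
11,1748.46
12,3547.51
13,2859.3
14,3253.2
15,3142.82
16,2668.08
17,2286.36
18,1975.7
19,1720.01
20,1507.64
21,1329.66
22,1179.28
23,1051.29
24,941.616
25,847.047
26,765.061
27,693.539
28,630.734
29,575.473
30,526.657
31,483.41
32,444.95
33,410.622
34,379.88
35,352.259
36,327.37
37,304.877
38,284.495
39,265.979
40,249.117
41,233.726
42,219.646
43,206.74
44,194.886
45,183.977
46,173.919
47,164.63
48,156.037
49,148.075
50,140.686
51,133.818
52,127.424
53,121.46
54,115.896
55,110.698
56,105.836
57,101.282
58,97.0135
59,93.0066
60,89.24
61,85.6959
62,82.3596
63,79.2106
64,76.2403
65,73.437
66,70.7891
67,68.2856
68,65.9168
69,63.6735
70,61.5474
71,59.5308
72,57.6166
73,55.7984
74,54.0699
75,52.4257
76,50.8607
77,49.3699
78,47.949
79,46.5939
80,45.3007
81,172.121
82,167.091
83,162.266
84,157.635
85,153.19
86,148.92
87,144.817
88,140.873
89,137.079
90,133.43
91,129.917
92,126.535
93,123.26
94,120.105
95,117.066
96,114.139
97,111.316
98,108.595
99,105.97
100,103.437
101,100.992
102,98.6306
103,96.35
104,94.1464
105,92.0166
106,89.9574
107,87.9658
108,86.0391
109,84.1746
110,82.3698
111,80.6222
112,78.9297
113,77.2899
114,75.7008
115,74.1487
116,72.6423
117,71.1824
118,69.767
119,68.3944
120,67.063
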