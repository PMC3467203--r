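age,annual_mortality_probability
65,0.0132
66,0.01446
67,0.01583
68,0.01734
69,0.01899
70,0.0208
71,0.02277
72,0.02493
73,0.02729
74,0.02987
75,0.0327
76,0.03604
77,0.03973
78,0.04379
79,0.04827
80,0.0532
81,0.05909
82,0.06562
83,0.07288
84,0.08095
85,0.0899
86,0.09986
87,0.11092
88,0.1232
89,0.13684
90,0.152
91,0.16671
92,0.18283
93,0.20052
94,0.21992
95,0.2412
96,0.2595
97,0.2792
98,0.30038
99,0.32318
100,0.3477
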