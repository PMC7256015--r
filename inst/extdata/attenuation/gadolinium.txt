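# material: gadolinium
# mass attenuation coefficient mu/rho vs photon energy
# columns: energy_keV  mu_over_rho_cm2_per_g
# analytic construction: exact Klein-Nishina incoherent scattering
# + per-branch power-law photoelectric/coherent term anchored at
# standard compilation (NIST XCOM) reference values
# K-edge at 50.24 keV; doubled points straddle the discontinuity
15        92.315
17.5      60.6783
20        42.2005
22.5      30.6452
25        23.0269
27.5      17.7882
30        14.06
32.5      11.3298
35        9.28165
37.5      7.71304
40        6.49
42.5      5.52136
45        4.74354
47.5      4.11122
50        3.59152
50.23     3.54846
50.25     17.7709
52.74     15.5499
55.24     13.6855
57.74     12.1146
60.24     10.781
62.74     9.64117
65.24     8.66081
67.74     7.8127
70.24     7.07505
72.74     6.43026
75.24     5.86403
77.74     5.36461
80.24     4.92233
82.74     4.52917
85.24     4.1784
87.74     3.86442
90.24     3.58245
92.74     3.32849
95.24     3.09909
97.74     2.89132
100.24    2.70266
102.74    2.53093
105.24    2.37426
107.74    2.23101
110.24    2.09975
112.74    1.97923
115.24    1.86838
117.74    1.76621
120.24    1.6719
122.74    1.58468
125.24    1.50389
127.74    1.42894
130.24    1.35931
132.74    1.29452
135.24    1.23416
137.74    1.17784
140.24    1.12523
142.74    1.07603
145.24    1.02995
147.74    0.986748
150       0.949984
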