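# material: gold
# mass attenuation coefficient mu/rho vs photon energy
# columns: energy_keV  mu_over_rho_cm2_per_g
# analytic construction: exact Klein-Nishina incoherent scattering
# + per-branch power-law photoelectric/coherent term anchored at
# standard compilation (NIST XCOM) reference values
# K-edge at 80.72 keV; doubled points straddle the discontinuity
15        175.136
17.5      116.321
20        81.617
22.5      59.7214
25        45.172
27.5      35.0964
30        27.88
32.5      22.5645
35        18.5554
37.5      15.4697
40        13.0527
42.5      11.1303
45        9.58028
47.5      8.3155
50        7.2723
52.5      6.40348
55        5.67352
57.5      5.05534
60        4.528
62.5      4.07514
65        3.68385
67.5      3.34384
70        3.04683
72.5      2.78612
75        2.55624
77.5      2.35267
80        2.17169
80.71     2.12397
80.73     8.92412
83.22     8.25402
85.72     7.6501
88.22     7.1064
90.72     6.61545
93.22     6.17087
95.72     5.76722
98.22     5.39979
100.72    5.06453
103.22    4.75792
105.72    4.4769
108.22    4.2188
110.72    3.98128
113.22    3.7623
115.72    3.56003
118.22    3.37288
120.72    3.19943
123.22    3.03842
125.72    2.88874
128.22    2.74938
130.72    2.61944
133.22    2.49814
135.72    2.38474
138.22    2.27859
140.72    2.17912
143.22    2.0858
145.72    1.99814
148.22    1.91572
150       1.86
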