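# material: iodine
# mass attenuation coefficient mu/rho vs photon energy
# columns: energy_keV  mu_over_rho_cm2_per_g
# analytic construction: exact Klein-Nishina incoherent scattering
# + per-branch power-law photoelectric/coherent term anchored at
# standard compilation (NIST XCOM) reference values
# K-edge at 33.17 keV; doubled points straddle the discontinuity
15        55.219
17.5      36.4118
20        25.4
22.5      18.4987
25        13.9399
27.5      10.7995
30        8.561
32.5      6.91928
33.16     6.55988
33.18     38.2975
35.67     31.3923
38.17     26.065
40.67     21.9022
43.17     18.5994
45.67     15.9434
48.17     13.7818
50.67     12.0036
53.17     10.5266
55.67     9.28899
58.17     8.24363
60.67     7.3542
63.17     6.59238
65.67     5.93583
68.17     5.36676
70.67     4.87092
73.17     4.43676
75.67     4.05486
78.17     3.7175
80.67     3.41829
83.17     3.15192
85.67     2.91394
88.17     2.70064
90.67     2.50883
93.17     2.33586
95.67     2.17942
98.17     2.03757
100.67    1.90862
103.17    1.79111
105.67    1.68378
108.17    1.58554
110.67    1.49543
113.17    1.41261
115.67    1.33636
118.17    1.26601
120.67    1.201
123.17    1.14082
125.67    1.08503
128.17    1.03323
130.67    0.985051
133.17    0.940186
135.67    0.898347
138.17    0.859277
140.67    0.822748
143.17    0.788551
145.67    0.756499
148.17    0.726424
150       0.705572
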