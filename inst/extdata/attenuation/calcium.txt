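# material: calcium
# mass attenuation coefficient mu/rho vs photon energy
# columns: energy_keV  mu_over_rho_cm2_per_g
# analytic construction: exact Klein-Nishina incoherent scattering
# + per-branch power-law photoelectric/coherent term anchored at
# standard compilation (NIST XCOM) reference values
# no K-edge in the tabulated range
15        4.20109
17.5      2.675
20        1.83
22.5      1.32534
25        1.00574
27.5      0.793601
30        0.647265
32.5      0.543014
35        0.466674
37.5      0.40943
40        0.3656
42.5      0.331417
45        0.304312
47.5      0.282497
50        0.2647
52.5      0.249997
55        0.237712
57.5      0.227336
60        0.218487
62.5      0.210868
65        0.204253
67.5      0.198462
70        0.193353
72.5      0.188815
75        0.184756
77.5      0.181102
80        0.177793
82.5      0.174781
85        0.172024
87.5      0.169487
90        0.167143
92.5      0.164967
95        0.162939
97.5      0.161042
100       0.159261
102.5     0.157583
105       0.155998
107.5     0.154496
110       0.153068
112.5     0.151709
115       0.15041
117.5     0.149168
120       0.147976
122.5     0.146832
125       0.14573
127.5     0.144668
130       0.143643
132.5     0.142652
135       0.141692
137.5     0.140762
140       0.139859
142.5     0.138981
145       0.138128
147.5     0.137298
150       0.136488
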