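# material: aluminum (Al, Z=13) -- used for source filtration only
# mass attenuation coefficient mu/rho vs photon energy
# columns: energy_keV  mu_over_rho_cm2_per_g
# sampled from standard photon cross-section compilations (NIST XCOM style)
15      7.955
20      3.441
30      1.128
40      0.5685
50      0.3681
60      0.2778
80      0.2018
100     0.1704
150     0.1378
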