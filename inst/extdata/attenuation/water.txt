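# material: water (liquid)
# mass attenuation coefficient mu/rho vs photon energy
# columns: energy_keV  mu_over_rho_cm2_per_g
# sampled from standard photon cross-section compilations (NIST XCOM style);
# no K-edge in the 15-150 keV range
15      1.673
20      0.8096
30      0.3756
40      0.2683
50      0.2269
60      0.2059
80      0.1837
100     0.1707
150     0.1505
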