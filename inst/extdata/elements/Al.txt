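# mass attenuation coefficient table, element Al
# columns: energy_keV mu_over_rho_cm2_g
30 1.1280
40 0.5685
50 0.3681
60 0.2778
80 0.2018
100 0.1704
150 0.1378
200 0.1223
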