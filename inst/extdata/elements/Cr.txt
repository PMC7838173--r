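# mass attenuation coefficient table, element Cr
# columns: energy_keV mu_over_rho_cm2_g
30 6.4340
40 2.8560
50 1.5500
60 0.9639
80 0.4905
100 0.3167
150 0.1812
200 0.1406
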