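# mass attenuation coefficient table, element Co
# columns: energy_keV mu_over_rho_cm2_g
30 9.0940
40 3.9810
50 2.1440
60 1.3140
80 0.6414
100 0.3949
150 0.2023
200 0.1476
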