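# mass attenuation coefficient table, element Ti
# columns: energy_keV mu_over_rho_cm2_g
30 4.9720
40 2.2140
50 1.2130
60 0.7661
80 0.4052
100 0.2721
150 0.1649
200 0.1314
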