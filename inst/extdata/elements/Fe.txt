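# mass attenuation coefficient table, element Fe
# columns: energy_keV mu_over_rho_cm2_g
30 8.1760
40 3.6290
50 1.9580
60 1.2050
80 0.5952
100 0.3717
150 0.1964
200 0.1460
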