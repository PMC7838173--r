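# mass attenuation coefficient table, element N
# columns: energy_keV mu_over_rho_cm2_g
30 0.2869
40 0.2219
50 0.1944
60 0.1789
80 0.1612
100 0.1505
150 0.1332
200 0.1214
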