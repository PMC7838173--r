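# mass attenuation coefficient table, element P
# columns: energy_keV mu_over_rho_cm2_g
30 1.7000
40 0.8096
50 0.4916
60 0.3494
80 0.2324
100 0.1865
150 0.1493
200 0.1316
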