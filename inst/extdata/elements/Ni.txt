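# mass attenuation coefficient table, element Ni
# columns: energy_keV mu_over_rho_cm2_g
30 10.340
40 4.6000
50 2.4740
60 1.5120
80 0.7306
100 0.4440
150 0.2208
200 0.1582
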