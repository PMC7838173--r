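# mass attenuation coefficient table, element Mo
# columns: energy_keV mu_over_rho_cm2_g
30 28.000
40 12.600
50 6.6800
60 4.0200
80 1.8500
100 1.0300
150 0.4200
200 0.2600
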