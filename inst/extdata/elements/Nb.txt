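# mass attenuation coefficient table, element Nb
# columns: energy_keV mu_over_rho_cm2_g
30 26.380
40 11.850
50 6.3000
60 3.8000
80 1.7500
100 0.9700
150 0.4000
200 0.2500
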