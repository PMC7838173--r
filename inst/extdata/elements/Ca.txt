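# mass attenuation coefficient table, element Ca
# columns: energy_keV mu_over_rho_cm2_g
30 3.9690
40 1.8300
50 1.0190
60 0.6578
80 0.3656
100 0.2567
150 0.1669
200 0.1421
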