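# calibration pellet: 200 mg/cm^3 hydroxyapatite mineral in a water-equivalent
# matrix at bulk density 1.13 g/cm^3 (weight fraction 0.200/1.13 = 0.177 HA,
# expanded to elements via Ca10(PO4)6(OH)2 stoichiometry)
name: ha_pellet
density_g_cm3: 1.13
composition:
  H: 0.0925
  O: 0.8042
  P: 0.0327
  Ca: 0.0706
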