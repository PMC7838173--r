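# wrought Ti-6Al-7Nb orthopaedic forging alloy
name: titanium_alloy
density_g_cm3: 4.52
composition:
  Ti: 0.87
  Al: 0.06
  Nb: 0.07
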