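# high-Cr/Ni wrought implant steel
name: stainless_steel
density_g_cm3: 7.95
composition:
  Fe: 0.63
  Cr: 0.20
  Ni: 0.15
  Mo: 0.02
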