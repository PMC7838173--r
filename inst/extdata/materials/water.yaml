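# gelatinous water box filling; 5% gelatin shifts attenuation by < 1% in the
# diagnostic range, so the surrogate is pure water
name: water
density_g_cm3: 1.00
composition:
  H: 0.1119
  O: 0.8881
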