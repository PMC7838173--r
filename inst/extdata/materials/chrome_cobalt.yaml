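# CoCrMo(Ni) heavy-duty forging alloy
name: chrome_cobalt
density_g_cm3: 8.30
composition:
  Co: 0.60
  Cr: 0.27
  Ni: 0.07
  Mo: 0.06
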