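symbol	Z
H	1
C	6
N	7
O	8
Al	13
P	15
Ca	20
Ti	22
Cr	24
Fe	26
Co	27
Ni	28
Nb	41
Mo	42
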