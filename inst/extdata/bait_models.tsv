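assembly	unit	leaf	inflorescence	bulb
narcissus_abyssmira	relative	1	30	45
galanthus_sp_abyssmira	RPM	0.01	33.3	140
galanthus_elwesii_abyssmira	RPM	2.24	22.6	71.7
galanthus_sp_trinity	TPM	2.42	29.0	94.7
galanthus_elwesii_trinity	TPM	16.0	49.3	202
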