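group	N	no_allele	only_DAB1	only_DAB3	both
bream	109	7	3	80	19
roach	97	3	15	34	45
hybrid	88	9	8	46	25
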