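property	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y	source
hydrophobicity	0.62	0.29	-0.90	-0.74	1.19	0.48	-0.40	1.38	-1.50	1.06	0.64	-0.78	0.12	-0.85	-2.53	-0.18	-0.05	1.08	0.81	0.26	Normalized consensus hydrophobicity scale (Eisenberg et al., J Mol Biol 179:125-142, 1984)
hydrophilicity	-0.5	-1.0	3.0	3.0	-2.5	0.0	-0.5	-1.8	3.0	-1.8	-1.3	0.2	0.0	0.2	3.0	0.3	-0.4	-1.5	-3.4	-2.3	Hydrophilicity scale (Hopp & Woods, PNAS 78:3824-3828, 1981)
mass	15.0	47.0	59.0	73.0	91.0	1.0	82.0	57.0	73.0	57.0	75.0	58.0	42.0	72.0	101.0	31.0	45.0	43.0	130.0	107.0	Side-chain mass in Da (rounded), as conventional in pseudo amino acid composition encodings
pK1	2.35	2.05	2.10	2.10	2.58	2.35	1.77	2.32	2.18	2.33	2.28	2.02	2.00	2.17	2.01	2.21	2.09	2.29	2.38	2.20	pK of the alpha-carboxyl group at 25 C (CRC Handbook of Chemistry and Physics)
pK2	9.87	10.25	9.82	9.47	9.24	9.78	9.18	9.76	8.95	9.74	9.21	8.80	10.60	9.13	9.99	9.15	9.10	9.72	9.39	9.11	pK of the alpha-amino group at 25 C (CRC Handbook of Chemistry and Physics)
pI	6.11	5.02	2.98	3.08	5.91	6.06	7.59	6.04	9.74	6.04	5.74	5.41	6.30	5.65	10.76	5.68	5.60	6.02	5.88	5.63	Isoelectric point at 25 C (CRC Handbook of Chemistry and Physics)
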