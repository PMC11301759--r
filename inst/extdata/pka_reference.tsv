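solute	pka_exp	model_pka_printed	dG	site_class
Arginine	13.8	8.57	-91.32	N
Histidine	6.0	6.19	-97.80	N
Lysine	10.7	10.71	-85.52	N
Ammonia	9.25	11.04	-84.62	N
Methylamine	10.65	10.77	-85.35	N
Pyridine	5.2	6.39	-97.26	N
Aniline	4.6	6.53	-96.88	N
Pyrrolidine	11.4	9.89	-87.75	N
Adenine	4.17	4.54	-102.29	N
Adenine (deprotonated)	9.65	9.00	-90.17	N
Aspartic acid	3.90	3.21	-105.89	O
Glutamic acid	4.07	5.11	-100.74	O
Tyrosine	10.1	8.08	-92.67	O
Water	14.0	14.19	-76.06	O
Hydrogen peroxide	11.75	13.75	-77.26	O
Formic acid	3.75	5.91	-98.57	O
Phenol	9.95	8.41	-91.76	O
Benzoic acid	4.20	5.16	-100.60	O
Oxalic acid	1.27	0.85	-112.30	O
Oxalic acid (deprotonated)	4.27	4.54	-102.29	O
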