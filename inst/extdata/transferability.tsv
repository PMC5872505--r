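species	amplified_dna	amplified_rna	amplified_total	pct_of_panel	pct_polymorphic_vs_wheat	pct_polymorphic_dna	pct_polymorphic_rna
Leymus racemosus	76	88	164	100	67	83	53
L. mollis	31	64	95	58	49	74	38
Psathyrostachys huashanica	23	55	78	48	44	70	33
Elymus ciliaris	17	49	66	40	32	42	29
Hordeum vulgare	5	31	36	22	2	20	16
H. bulbosum	8	31	39	24	23	25	23
Dasypyrum villosum	9	39	48	29	21	33	18
Secale cereale	9	38	47	29	15	11	16
Triticum urartu	9	36	45	27	7	0	8
Aegilops speltoides	8	39	47	29	6	13	5
Ae. tauschii	10	39	49	30	0	0	0
T. aestivum	10	51	61	37	NA	NA	NA
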