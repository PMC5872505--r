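alien_chromosome	1A	1B	1D	2A	2B	2D	3A	3B	3D	4A	4B	4D	5A	5B	5D	6A	6B	6D	7A	7B	7D	reported_group
Lr#A	3	1	1	75	71	198	3	0	4	0	2	2	1	0	5	1	3	5	2	3	1	2
Lr#E	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	ND
Lr#F	4	2	3	1	2	5	0	0	0	77	79	141	2	1	2	2	0	0	20	3	12	4
Lr#H	1	2	7	0	2	2	68	94	204	2	2	4	3	1	2	0	6	2	0	4	4	3
Lr#I	3	0	5	3	1	4	1	1	5	2	7	9	74	162	193	4	2	4	3	6	2	5
Lr#J	10	3	4	2	5	2	2	4	1	2	2	4	5	7	2	0	3	5	84	105	208	7
Lr#K	4	2	4	1	3	7	1	2	2	0	2	6	2	2	6	81	117	205	5	8	9	6
Lr#L	1	0	1	135	158	293	16	6	3	3	2	2	7	9	0	3	6	1	1	5	5	2
Lr#N	4	6	3	0	1	4	77	131	176	3	0	0	1	3	3	0	2	1	2	4	5	3
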