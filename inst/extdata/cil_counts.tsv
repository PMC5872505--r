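alien_chromosome	common	line_specific
Lr#A	99	355
Lr#E	79	38
Lr#F	70	173
Lr#H	86	109
Lr#I	74	46
Lr#J	68	130
Lr#K	61	186
Lr#L	92	124
Lr#N	81	110
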