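alien_chromosome	pcr_total	dart_total	specific_pcr	specific_dart	specific_total
Lr#A	14	434	6	381	387
Lr#E	4	46	1	1	2
Lr#F	10	499	4	344	348
Lr#H	20	528	12	410	422
Lr#I	12	558	4	491	495
Lr#J	17	511	9	450	459
Lr#K	12	519	7	465	472
Lr#L	18	647	8	525	533
Lr#N	16	549	5	428	433
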