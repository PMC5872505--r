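line	pcr_short	pcr_long	dart_short	dart_long	reported_call
NR1	0	0	0	2	uncertain
NR2	2	0	160	0	short
NR3	0	0	67	0	short
NR4	0	1	0	48	long
NR5	2	0	158	0	short
NR6	2	0	162	0	short
NR7	0	3	0	248	long
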