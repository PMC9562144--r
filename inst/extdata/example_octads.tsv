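cross_id	ascus_id	spore_index	viable	genotype
wtf25_het	octad_01	A	0	.
wtf25_het	octad_01	B	0	.
wtf25_het	octad_01	C	0	.
wtf25_het	octad_01	D	0	.
wtf25_het	octad_01	E	1	S
wtf25_het	octad_01	F	1	S
wtf25_het	octad_01	G	1	S
wtf25_het	octad_01	H	1	S
wtf25_het	octad_02	A	1	R
wtf25_het	octad_02	B	0	.
wtf25_het	octad_02	C	0	.
wtf25_het	octad_02	D	0	.
wtf25_het	octad_02	E	1	S
wtf25_het	octad_02	F	1	S
wtf25_het	octad_02	G	1	S
wtf25_het	octad_02	H	1	S
wtf25_het	octad_03	A	0	.
wtf25_het	octad_03	B	0	.
wtf25_het	octad_03	C	0	.
wtf25_het	octad_03	D	0	.
wtf25_het	octad_03	E	1	S
wtf25_het	octad_03	F	1	S
wtf25_het	octad_03	G	1	S
wtf25_het	octad_03	H	1	S
wtf25_het	octad_04	A	1	R
wtf25_het	octad_04	B	1	R
wtf25_het	octad_04	C	0	.
wtf25_het	octad_04	D	0	.
wtf25_het	octad_04	E	1	S
wtf25_het	octad_04	F	1	S
wtf25_het	octad_04	G	1	S
wtf25_het	octad_04	H	1	S
wtf25_het	octad_05	A	1	R
wtf25_het	octad_05	B	1	R
wtf25_het	octad_05	C	1	R
wtf25_het	octad_05	D	1	R
wtf25_het	octad_05	E	1	S
wtf25_het	octad_05	F	1	S
wtf25_het	octad_05	G	1	S
wtf25_het	octad_05	H	1	S
wtf25_het	octad_06	A	0	.
wtf25_het	octad_06	B	0	.
wtf25_het	octad_06	C	0	.
wtf25_het	octad_06	D	0	.
wtf25_het	octad_06	E	1	S
wtf25_het	octad_06	F	1	S
wtf25_het	octad_06	G	1	S
wtf25_het	octad_06	H	0	.
wtf25_het	octad_07	A	1	R
wtf25_het	octad_07	B	0	.
wtf25_het	octad_07	C	0	.
wtf25_het	octad_07	D	0	.
wtf25_het	octad_07	E	1	S
wtf25_het	octad_07	F	1	S
wtf25_het	octad_07	G	1	S
wtf25_het	octad_07	H	1	S
wtf25_het	octad_08	A	1	R
wtf25_het	octad_08	B	0	.
wtf25_het	octad_08	C	0	.
wtf25_het	octad_08	D	1	S
wtf25_het	octad_08	E	1	S
wtf25_het	octad_08	F	1	S
wtf25_het	octad_08	G	1	S
wtf25_het	octad_09	A	1	R
wtf25_het	octad_09	B	1	R
wtf25_het	octad_09	C	1	S
wtf25_het	octad_09	D	1	S
wtf25_het	octad_09	E	1	S
wtf25_het	octad_09	F	1	S
wtf25_het	octad_10	A	1	R
wtf25_het	octad_10	B	1	R
wtf25_het	octad_10	C	1	R
wtf25_het	octad_10	D	1	R
wtf25_het	octad_10	E	1	R
wtf25_het	octad_10	F	1	S
wtf25_het	octad_10	G	1	S
wtf25_het	octad_10	H	1	S
wt_control	octad_01	A	1	S
wt_control	octad_01	B	1	S
wt_control	octad_01	C	1	S
wt_control	octad_01	D	1	S
wt_control	octad_01	E	1	S
wt_control	octad_01	F	1	S
wt_control	octad_01	G	1	S
wt_control	octad_01	H	1	S
wt_control	octad_02	A	0	.
wt_control	octad_02	B	1	S
wt_control	octad_02	C	1	S
wt_control	octad_02	D	1	S
wt_control	octad_02	E	1	S
wt_control	octad_02	F	1	S
wt_control	octad_02	G	1	S
wt_control	octad_02	H	1	S
wt_control	octad_03	A	1	S
wt_control	octad_03	B	1	S
wt_control	octad_03	C	1	S
wt_control	octad_03	D	1	S
wt_control	octad_03	E	1	S
wt_control	octad_03	F	1	S
wt_control	octad_03	G	1	S
wt_control	octad_03	H	1	S
wt_control	octad_04	A	1	S
wt_control	octad_04	B	1	S
wt_control	octad_04	C	1	S
wt_control	octad_04	D	1	S
wt_control	octad_04	E	1	S
wt_control	octad_04	F	1	S
wt_control	octad_04	G	1	S
wt_control	octad_04	H	1	S
wt_control	octad_05	A	1	S
wt_control	octad_05	B	1	S
wt_control	octad_05	C	1	S
wt_control	octad_05	D	1	S
wt_control	octad_05	E	0	.
wt_control	octad_05	F	1	S
wt_control	octad_05	G	1	S
wt_control	octad_05	H	1	S
wt_control	octad_06	A	1	S
wt_control	octad_06	B	1	S
wt_control	octad_06	C	1	S
wt_control	octad_06	D	1	S
wt_control	octad_06	E	1	S
wt_control	octad_06	F	1	S
wt_control	octad_06	G	1	S
wt_control	octad_06	H	1	S
wt_control	octad_07	A	1	S
wt_control	octad_07	B	1	S
wt_control	octad_07	C	1	S
wt_control	octad_07	D	1	S
wt_control	octad_07	E	1	S
wt_control	octad_07	F	1	S
wt_control	octad_07	G	1	S
wt_control	octad_07	H	1	S
wt_control	octad_08	A	1	S
wt_control	octad_08	B	1	S
wt_control	octad_08	C	1	S
wt_control	octad_08	D	1	S
wt_control	octad_08	E	1	S
wt_control	octad_08	F	1	S
wt_control	octad_08	G	1	S
wt_control	octad_08	H	1	S
wt_control	octad_09	A	0	.
wt_control	octad_09	B	1	S
wt_control	octad_09	C	1	S
wt_control	octad_09	D	1	S
wt_control	octad_09	E	1	S
wt_control	octad_09	F	1	S
wt_control	octad_09	G	1	S
wt_control	octad_09	H	1	S
wt_control	octad_10	A	0	.
wt_control	octad_10	B	1	S
wt_control	octad_10	C	1	S
wt_control	octad_10	D	1	S
wt_control	octad_10	E	1	S
wt_control	octad_10	F	1	S
wt_control	octad_10	G	1	S
wt_control	octad_10	H	1	S
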