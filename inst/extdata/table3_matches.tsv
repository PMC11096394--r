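haplotype	haplogroup	NW	NA	IP	FR	IT	other	asterisk
067	HV1	11	12	37	1	0		0
086	H1	6	20	149	0	10		0
213	H/HV/U/R	21	12	45	48	26		0
223	H	1	19	299	0	2		0
265	HV/R	16	1	49	0	24		0
302	H1	0	0	9	0	19		1
172 278	H1	1	0	65	0	1		0
145 213	H/HV/U/R	1	0	0	0	0		0
260 278	H1cf	0	0	0	0	0	Yemen	0
129 294	H/HV/U/R	0	0	0	0	9	Frisian	1
316	HV	0	0	0	0	0	Iran	0
189 316	HV	0	0	7	0	3	Iran	1
069	J1c3	0	0	13	0	19		1
126 294	T2e1	1	19	379	0	24		0
126 224 292 294	T2c1d3	0	0	0	0	0	Romania	0
126 255 292 294	T2c1d3	0	0	0	0	0		0
126 292 294 362	T2c1d3	0	0	0	0	0	Iraq	0
126 154 163 186 189 294	T1a	5	3	0	0	0		0
270 294	U5a2a	4	0	1	0	0		0
239 278	U6a1a1	0	0	1	0	0		1
172 219 221 224 278	U6a	0	0	0	0	0		0
169 172 189	U6c1	63	44	5	4	4		0
129 169 172 189 213	U6c1	0	0	0	0	0		0
309 318T	U7	0	0	29	0	24		1
145 176G 223 297 311	N1b1a7	0	0	0	0	0	Armenia	0
111 189 223 278	X3a	0	0	13	0	0		1
126 223 262 320	L3e2b	0	0	0	0	0		0
223 278 390	L2	6	19	0	0	0		0
223 239 278 292	L2e	0	0	0	0	0		0
111A 145 184 223 239 278 292 311 355 390 399 400	L2e	0	0	0	0	0	Senegal	0
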