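region	variants	count
IP	126	149
FR	126	3
IT	126	5
IP	239	149
IT	239	10
IP	292	89
IT	292	3
IP	316	13
IT	316	10
IP	069 126 278 366	8
IT	069 126 278 366	9
IP	163 172 219 311	4
IT	163 172 219 311	3
IP	223 292 295	35
IT	223 292 295	10
NW	067	11
NA	067	12
IP	067	37
FR	067	1
NW	086	6
NA	086	20
IP	086	149
IT	086	10
NW	213	21
NA	213	12
IP	213	45
FR	213	48
IT	213	26
NW	223	1
NA	223	19
IP	223	299
IT	223	2
NW	265	16
NA	265	1
IP	265	49
IT	265	24
IP	302	9
IT	302	19
NW	172 278	1
IP	172 278	65
IT	172 278	1
NW	145 213	1
IT	129 294	9
IP	189 316	7
IT	189 316	3
IP	069	13
IT	069	19
NW	126 294	1
NA	126 294	19
IP	126 294	379
IT	126 294	24
NW	126 154 163 186 189 294	5
NA	126 154 163 186 189 294	3
NW	270 294	4
IP	270 294	1
IP	239 278	1
NW	169 172 189	63
NA	169 172 189	44
IP	169 172 189	5
FR	169 172 189	4
IT	169 172 189	4
IP	309 318T	29
IT	309 318T	24
IP	111 189 223 278	13
NW	223 278 390	6
NA	223 278 390	19
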