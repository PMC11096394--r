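haplogroup	parent	motif
ROOT
R	ROOT
HV	R
HV1	HV	067
HV-316	HV	316
H	HV
H1	H
H1-239	H1	239
H1-292	H1	292
H1ao	H1	278
H1bw	H1	316
H1cf	H1	260
H1e	H1
H1e1a	H1e	5460
H1e1a9	H1e1a	13934
H3	H
H3r	H3	126
H3v	H3	192 260
H4a1	H
H4a1e	H4a1	362
J	R	069 126
J1c	J
J1c1	J1c	255
J1c2	J1c	7963
J1c2c2	J1c2	6554
J1c2e2	J1c2	278 366
J1c3	J1c	13934
J2a2d1	J	319
T	R	126 294
T1	T	163 186 189
T1a	T1	154
T2	T	296
T2b	T2	304
T2e1	T
T2c	T	292
T2c1d3	T2c	7697
T2c1d1c	T2c	262
U	R
U5	U	192 270
U5a	U5	256
U5a1b4	U5a	093 362
U5a2a	U5	294
U5b1	U5	189
U6	U	172 219
U6a	U6	278
U6a1a1	U6a	239
U6a3a1	U6a	9320
U6a7	U6a	221 224 311
U6a7a1b	U6a7	12618
U6b	U6	311
U6b1a	U6b	163
U6b1a1	U6b1a	5300
U6b1b	U6b	5315
U6c	U	169 172 189
U6c1	U6c	129
U7	U	309 318T
W	R	223 292
W1e1	W	295
X	R	189 223 278
X3a	X	111
N1b1a7	R	145 176G 223 297 311
L3	ROOT	223
M1	L3	129 189 249
L3b	L3	124 278 362
L3b1a	L3b	@124 311
L3b1a11	L3b1a	4218
L3b1a12	L3b1a	8697 9947 10646 11257 14136 14553
L3d	L3	124
L3d1b	L3d	256
L3d1b3a	L3d1b	311
L3e2	L3	320
L3e2b	L3e2	2483
L2	ROOT	223 278 390
L2b1a	L2	114A 129 213 311 355 362
L2e	L2	111A 145 184 239 292 311 355 399 400
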