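id	variants	hg_before	most_probable	contaminator	hg_after	region
t01	093 192	H/HV/U/R	093 192 (256 270 362)	Incomplete	U5a1b4	IP (68)
t02	129 294	H/HV/U/R	(126) 129 294 (296 304)	Incomplete	T2b	IP (75)
t03	145 213	H/HV/U/R	145 213 (223 278 294 390)	Incomplete	L2	NWA (11)
t04	126 255 292 294	T2c1d3	126 292 294	069 126 255	T2c1d3	NWA (11)
t05	239 278	U*	(172 219) 239 278	Incomplete	U6a1a1	NWA (30)
t06	172 219 221 224 278	U6a	172 219 278	221 224 311	U6a7	NWA (6)
t07	129 169 172 189 213	U6c	129 169 172 189	213	U6c1	NWA (42)
t08	126 223 262 320	L3e2b	223 320	126 262 292 294	L3e2	NA (70)
t09	223 239 278 292	L3	(111A 145 184) 223 239 278 292 (311 355 390)	Incomplete	L2e	Senegal (6)
t10	223 278 311 355 362	L3b1a12	(114A 129 213) 223 278 311 355 362	Incomplete	L2b1a	Mali (71)
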