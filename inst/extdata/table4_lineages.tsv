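lineage	group	period	mean_age	ci_lo	ci_hi	islands_group	origin
H1cf	1					Western	Algeria
H1e1a	1					Eastern	Italy
J2a2d1	1	124 AD	1876	1426	2325	Western	Tunisia
U6b1a	1					Western	Morocco
U6c1	1					Eastern	Italy, Morocco
W1e1	2					Western	Italy
X3a	2	1117 AD	883	809	956	Western	North Africa
U5a1b4	2					Western	France
U6b1a1	2					Canarian	Autochthonous
U6a*	3					Eastern	North Africa
H4a1	3					Eastern	North Africa
L2e	3					Western	Senegal
T2c1d3	3	1430 AD	570	435	704	Eastern	North Africa
L3d1b3a	3					Western	Morocco
T2c1d1c	3					Eastern	Autochthonous
L3b1a	3					Eastern	Unknown
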