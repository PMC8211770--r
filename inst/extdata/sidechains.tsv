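code	Hex	Pent	dHex	HexA	terminal	trim
G	0	0	0	0
X	0	1	0	0
L	1	1	0	0	Hex	X
F	1	1	1	0	dHex	L
S	0	2	0	0
D	0	2	0	0
E	0	2	1	0	dHex	D
B	0	2	0	0
Y	0	1	0	1
P	1	1	0	1	Hex	Y
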