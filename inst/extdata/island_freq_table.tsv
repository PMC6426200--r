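haplogroup	HIE	PAL	TFE	GOM	GCA	LAN&FUE
H	12	10	15	2	33	13
H1cf	57	8	6	2	1	0
H4a1e	0	0	0	0	3	1
HV0	0	0	1	0	0	0
J	0	3	4	5	2	0
K	0	1	1	1	2	0
L1/L2	0	2	2	1	1	0
L3	0	0	2	4	1	0
L3b1a12	0	0	0	0	5	0
M1	0	0	0	0	1	0
Other T	0	1	0	0	3	0
T2c1	0	3	12	0	15	2
U5	0	0	0	0	3	1
U6a	0	0	2	0	6	2
U6b	0	2	8	38	4	0
U6c	0	0	0	0	5	1
U7	1	0	0	0	0	0
W1e1	0	1	0	0	0	0
X3a	0	4	0	4	2	0
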