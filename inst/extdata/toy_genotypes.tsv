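id	ploidy	locA	locB
P1	2	101,103	A,A
P2	2	101,101	A,C
C1	2	101,103	A,C
C2	2	101,101	A,A
U1	2	103,103	C,C
U2	2	101,103	A,C
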