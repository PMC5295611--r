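id	P1	P2	C1	C2	U1	U2
P1	0.5	0	0.25	0.25	0	0
P2	0	0.5	0.25	0.25	0	0
C1	0.25	0.25	0.5	0.25	0	0
C2	0.25	0.25	0.25	0.5	0	0
U1	0	0	0	0	0.5	0.5
U2	0	0	0	0	0.5	0.5
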