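id father mother sex
P1 0 0 1
P2 0 0 2
C1 P1 P2 1
C2 P1 P2 2
U1 0 0 1
U2 0 0 2
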