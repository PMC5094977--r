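condition	marker	direction
HEL+JAKi	STAT5	down
HEL+JAKi	AKT1	down
HEL+JAKi	ERK	down
HEL+JAKi	PARPc	up
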