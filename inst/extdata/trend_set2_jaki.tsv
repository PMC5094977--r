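condition	marker	direction
SET2+JAKi	PARPc	up
SET2+JAKi	CASP3	up
SET2+JAKi	CASP7	up
SET2+JAKi	CASP8	up
SET2+JAKi	CASP9	up
SET2+JAKi	BIM	up
SET2+JAKi	STAT5	down
SET2+JAKi	MCL1	down
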