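format: avatarnet-v1

[nodes]
id	label	roles	y_max	tau	basal_drive	y0
IL6	IL6	ligand	1	1000	0.00	0
TNFA	TNFA	ligand	1	1000	0.00	0
IFNG	IFNG	ligand	1	1000	0.00	0
EGF	EGF	ligand	1	1000	0.00	0
IL6R	IL6R	receptor	1	1000	0.10	0
TNFR	TNFR	receptor	1	1000	0.10	0
IFNGR	IFNGR	receptor	1	1000	0.10	0
JAK2	JAK2	kinase	1	1000	0.30	0
JAK1	JAK1	kinase	1	1000	0.20	0
JAK3	JAK3	kinase	1	1000	0.10	0
TYK2	TYK2	kinase	1	1000	0.10	0
STAT5	STAT5	transcription_factor	1	1000	0.05	0
STAT3	STAT3	transcription_factor	1	1000	0.05	0
STAT1	STAT1	transcription_factor	1	1000	0.05	0
NFKB	NFKB	transcription_factor	1	1000	0.10	0
PI3K	PI3K	kinase	1	1000	0.10	0
AKT1	AKT1	kinase	1	1000	0.05	0
RPTOR	RPTOR	effector	1	1000	0.30	0
SHC1	SHC1	effector	1	1000	0.10	0
MAP2K1	MAP2K1	kinase	1	1000	0.05	0
ERK	ERK	kinase	1	1000	0.05	0
TP53	TP53	transcription_factor	1	1000	0.40	0
CDKN2A	CDKN2A	effector	1	1000	0.35	0
RB1	RB1	effector	1	1000	0.60	0
E2F1	E2F1	transcription_factor	1	1000	0.30	0
NOTCH2	NOTCH2	receptor	1	1000	0.20	0
CCND1	CCND1	effector	1	1000	0.10	0
CCNE1	CCNE1	effector	1	1000	0.05	0
CCNA2	CCNA2	effector	1	1000	0.05	0
CCNB1	CCNB1	effector	1	1000	0.10	0
CDK4	CDK4	kinase	1	1000	0.60	0
CDK2	CDK2	kinase	1	1000	0.60	0
CDK1	CDK1	kinase	1	1000	0.60	0
CDK4_CCND1	CDK4_CCND1	complex,readout	1	1000	0.00	0
CDK2_CCNE1	CDK2_CCNE1	complex,readout	1	1000	0.00	0
CDK2_CCNA2	CDK2_CCNA2	complex,readout	1	1000	0.00	0
CDK1_CCNB1	CDK1_CCNB1	complex,readout	1	1000	0.00	0
BCL2	BCL2	effector,readout	1	1000	0.10	0
BCL2L1	BCL2L1	effector	1	1000	0.10	0
MCL1	MCL1	effector,readout	1	1000	0.10	0
BIRC5	BIRC5	effector,readout	1	1000	0.05	0
BIRC2	BIRC2	effector,readout	1	1000	0.10	0
XIAP	XIAP	effector,readout	1	1000	0.10	0
BIM	BIM	effector,readout	1	1000	0.30	0
BAX	BAX	effector,readout	1	1000	0.35	0
NOXA	NOXA	effector,readout	1	1000	0.05	0
CASP8	CASP8	effector,readout	1	1000	0.20	0
CASP9	CASP9	effector,readout	1	1000	0.15	0
CASP3	CASP3	effector,readout	1	1000	0.10	0
CASP7	CASP7	effector,readout	1	1000	0.10	0
PARPc	PARPc	effector,readout	1	1000	0.05	0

[interactions]
source	target	sign	weight	half_max	hill	gate
IL6	IL6R	activating	0.90	0.50	1.4	OR
TNFA	TNFR	activating	0.90	0.50	1.4	OR
IFNG	IFNGR	activating	0.90	0.50	1.4	OR
IL6R	JAK1	activating	0.50	0.50	1.4	OR
IL6R	JAK2	activating	0.30	0.50	1.4	OR
IFNGR	JAK1	activating	0.50	0.50	1.4	OR
IFNGR	JAK2	activating	0.30	0.50	1.4	OR
TNFR	NFKB	activating	0.35	0.50	1.4	OR
TNFR	CASP8	activating	0.55	0.50	1.4	OR
JAK2	STAT5	activating	0.90	0.50	1.4	OR
JAK2	STAT3	activating	0.60	0.50	1.4	OR
JAK2	STAT1	activating	0.30	0.50	1.4	OR
JAK2	PI3K	activating	0.60	0.50	1.4	OR
JAK2	SHC1	activating	0.60	0.50	1.4	OR
JAK1	STAT3	activating	0.40	0.50	1.4	OR
JAK1	STAT1	activating	0.50	0.50	1.4	OR
JAK3	STAT5	activating	0.20	0.50	1.4	OR
TYK2	STAT1	activating	0.20	0.50	1.4	OR
EGF	SHC1	activating	0.50	0.50	1.4	OR
PI3K	AKT1	activating	0.85	0.50	1.4	OR
SHC1	MAP2K1	activating	0.80	0.50	1.4	OR
MAP2K1	ERK	activating	0.85	0.50	1.4	OR
AKT1	RPTOR	activating	0.40	0.50	1.4	OR
STAT5	BCL2	activating	0.60	0.50	1.4	OR
STAT5	MCL1	activating	0.60	0.50	1.4	OR
STAT5	BCL2L1	activating	0.50	0.50	1.4	OR
STAT5	BIRC5	activating	0.50	0.50	1.4	OR
STAT5	BIRC2	activating	0.50	0.50	1.4	OR
STAT5	CCND1	activating	0.50	0.50	1.4	OR
STAT3	MCL1	activating	0.40	0.50	1.4	OR
STAT3	BCL2	activating	0.30	0.50	1.4	OR
STAT3	CCND1	activating	0.30	0.50	1.4	OR
STAT3	BIRC5	activating	0.30	0.50	1.4	OR
STAT1	MCL1	activating	0.20	0.50	1.4	OR
NFKB	XIAP	activating	0.15	0.50	1.4	OR
NFKB	BIRC2	activating	0.15	0.50	1.4	OR
NFKB	BCL2	activating	0.15	0.50	1.4	OR
NFKB	CCND1	activating	0.20	0.50	1.4	OR
AKT1	XIAP	activating	0.50	0.50	1.4	OR
STAT5	XIAP	activating	0.25	0.50	1.4	OR
ERK	CCND1	activating	0.50	0.50	1.4	OR
RPTOR	CCND1	activating	0.30	0.50	1.4	OR
NOTCH2	CCND1	activating	0.20	0.50	1.4	OR
AKT1	BIM	inhibiting	0.50	0.50	1.4	OR
ERK	BIM	inhibiting	0.60	0.50	1.4	OR
AKT1	CASP9	inhibiting	0.35	0.50	1.4	OR
CDKN2A	TP53	activating	0.40	0.50	1.4	OR
TP53	BAX	activating	0.50	0.50	1.4	OR
TP53	NOXA	activating	0.60	0.50	1.4	OR
RB1	E2F1	inhibiting	0.75	0.50	1.4	OR
E2F1	CCNE1	activating	0.60	0.50	1.4	OR
E2F1	CCNA2	activating	0.60	0.50	1.4	OR
E2F1	CCNB1	activating	0.40	0.50	1.4	OR
CDK4	CDK4_CCND1	activating	0.95	0.50	1.4	AND
CCND1	CDK4_CCND1	activating	0.95	0.50	1.4	AND
CDK2	CDK2_CCNE1	activating	0.95	0.50	1.4	AND
CCNE1	CDK2_CCNE1	activating	0.95	0.50	1.4	AND
CDK2	CDK2_CCNA2	activating	0.95	0.50	1.4	AND
CCNA2	CDK2_CCNA2	activating	0.95	0.50	1.4	AND
CDK1	CDK1_CCNB1	activating	0.95	0.50	1.4	AND
CCNB1	CDK1_CCNB1	activating	0.95	0.50	1.4	AND
CDKN2A	CDK4_CCND1	inhibiting	0.50	0.50	1.4	OR
CDK4_CCND1	RB1	inhibiting	0.50	0.50	1.4	OR
CDK2_CCNE1	RB1	inhibiting	0.30	0.50	1.4	OR
BIM	BAX	activating	0.50	0.50	1.4	OR
CASP8	BAX	activating	0.50	0.40	1.4	OR
BCL2	BAX	inhibiting	0.75	0.35	1.4	OR
BCL2L1	BAX	inhibiting	0.50	0.35	1.4	OR
MCL1	BAX	inhibiting	0.55	0.35	1.4	OR
NOXA	MCL1	inhibiting	0.45	0.50	1.4	OR
BAX	CASP9	activating	0.90	0.35	1.4	OR
XIAP	CASP9	inhibiting	0.50	0.40	1.4	OR
BIRC5	CASP9	inhibiting	0.35	0.50	1.4	OR
CASP9	CASP3	activating	0.85	0.40	1.4	OR
CASP8	CASP3	activating	0.55	0.50	1.4	OR
XIAP	CASP3	inhibiting	0.90	0.35	2.0	OR
CASP3	CASP7	activating	0.60	0.50	1.4	OR
XIAP	CASP7	inhibiting	0.30	0.50	1.4	OR
CASP3	PARPc	activating	0.85	0.50	1.4	OR
CASP7	PARPc	activating	0.30	0.50	1.4	OR
BIRC2	CASP8	inhibiting	0.97	0.30	2.0	OR

[boundary_ligands]
IL6
TNFA
IFNG
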