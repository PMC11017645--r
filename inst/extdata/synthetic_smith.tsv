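1	C
2	CC
3	CCC
Q1	CO
Q2	CCO
QY	CC(C)O
QX	CC(C)(C)O
1Y1	CC(C)C
1V1	CC(C)=O
1VQ	CC(=O)O
1OV1	COC(C)=O
2O2	CCOCC
1S1	CSC
1M1	CNC
1N1&1	CN(C)C
ZY	CC(C)N
ZVZ	NC(=O)N
Z2Z	NCCN
Z2Z &GH	NCCN.Cl
G1G	ClCCl
G2G	ClCCCl
E2E	BrCCBr
G1	CCl
GH	Cl
QQ	OO
OO	O=O
SCN	SC#N
1UU1	C#C
1UU2	CC#C
2U2	CC=CC
WN3	CCC[N](=O)=O
1NW	C[N](=O)=O
-SE-H	[SeH2]
Q1XGG2Y1Q1Z	OCC(Cl)(Cl)CCC(CO)CN
Z1Y1Q2X1QGG	OCC(Cl)(Cl)CCC(CO)CN
K	C[N+](C)(C)C
R	c1ccccc1
1R	Cc1ccccc1
GR	Clc1ccccc1
QR	Oc1ccccc1
ZR	Nc1ccccc1
Q1R	OCc1ccccc1
QVR	OC(=O)c1ccccc1
1VR	CC(=O)c1ccccc1
RVR	O=C(c1ccccc1)c1ccccc1
L6J	c1ccccc1
L6TJ	C1CCCCC1
L5TJ	C1CCCC1
T6NJ	c1ccncc1
T5MJ	c1cc[nH]c1
T5OJ	c1ccoc1
T5SJ	c1ccsc1
T6N CNJ	c1cncnc1
T6O DOTJ	C1COCCO1
L66J	c1ccc2ccccc2c1
L C666J	c1ccc2cc3ccccc3cc2c1
L B666J	c1ccc2ccc3ccccc3c2c1
T66 BNJ	c1ccc2ncccc2c1
T56 BMJ	c1ccc2c(c1)cc[nH]2
L6TJ A1	CC1CCCCC1
L5TJ A&- AL5TJ	C1CCC2(C1)CCCC2
T-T665 B6 2AB O KO NUT &TTJ IQ MQ B2N1 &- D6J	CN1CCC23c4c5ccc(O)c4OC2C(O)C=CC3C1C5
T B65 H6 F6 F6 3FGH R AO DU GX PN HU- MTT &TTJ CQ JQ P1	CN1CCC23c4c5ccc(O)c4OC2C(O)C=CC3C1C5
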