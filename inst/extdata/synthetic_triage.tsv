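SCN	SC#N
Q1XGG2Y1Q1Z	OCC(Cl)(Cl)CCC(CO)CN
Z2Z & GH	NCCN.Cl
SCUUN	SC#N
Q2 &&beta form	CCO
prepared Q1XGG2Y1Q1Z in two steps	OCC(Cl)(Cl)CCC(CO)CN
mixture of isomers	CCO
Q2	CCCCCCCC
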