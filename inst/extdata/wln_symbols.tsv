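char	meaning	max_branches	exact_branches	expandable	terminating	locant_capable	implied_charge	implied_fill	must_unsaturate
A	locant only	0	FALSE	FALSE	FALSE	TRUE	0	hydrogen	FALSE
B	boron	3	FALSE	FALSE	FALSE	TRUE	0	hydrogen	FALSE
C	carbon	4	TRUE	FALSE	FALSE	TRUE	0	hydrogen	TRUE
D	open chelate	0	FALSE	FALSE	FALSE	TRUE	0	hydrogen	FALSE
E	bromine	1	FALSE	FALSE	TRUE	TRUE	0	hydrogen	FALSE
F	fluorine	1	FALSE	FALSE	TRUE	TRUE	0	hydrogen	FALSE
G	chlorine	1	FALSE	FALSE	TRUE	TRUE	0	hydrogen	FALSE
H	hydrogen	1	FALSE	FALSE	TRUE	TRUE	0	hydrogen	FALSE
I	iodine	1	FALSE	FALSE	TRUE	TRUE	0	hydrogen	FALSE
J	ring closure	0	FALSE	FALSE	TRUE	TRUE	0	hydrogen	FALSE
K	nitrogen (1+, 4 implied methyls)	4	FALSE	FALSE	FALSE	TRUE	1	methyl	FALSE
L	open carbocycle	0	FALSE	FALSE	FALSE	TRUE	0	hydrogen	FALSE
M	secondary amine (NH)	2	FALSE	FALSE	FALSE	TRUE	0	hydrogen	FALSE
N	nitrogen	3	FALSE	FALSE	FALSE	TRUE	0	hydrogen	FALSE
O	oxygen	2	FALSE	FALSE	FALSE	TRUE	0	hydrogen	FALSE
P	phosphorus	3	FALSE	FALSE	FALSE	TRUE	0	hydrogen	FALSE
Q	hydroxyl	1	FALSE	FALSE	TRUE	TRUE	0	hydrogen	FALSE
R	benzene	1	FALSE	TRUE	FALSE	TRUE	0	hydrogen	FALSE
S	sulphur	3	FALSE	FALSE	FALSE	TRUE	0	hydrogen	FALSE
T	open heterocycle	0	FALSE	FALSE	FALSE	TRUE	0	hydrogen	FALSE
U	unsaturate bond	0	FALSE	FALSE	FALSE	TRUE	0	hydrogen	FALSE
V	carbonyl	2	FALSE	FALSE	FALSE	TRUE	0	hydrogen	FALSE
W	add -oxylate (dioxo)	0	FALSE	FALSE	FALSE	TRUE	0	hydrogen	FALSE
X	carbon (4 implied methyls)	4	FALSE	FALSE	FALSE	TRUE	0	methyl	FALSE
Y	carbon (3 implied methyls)	3	FALSE	FALSE	FALSE	FALSE	0	methyl	FALSE
Z	primary amine (NH2)	0	FALSE	FALSE	TRUE	FALSE	0	hydrogen	FALSE
0	alkane chain of length n	0	FALSE	FALSE	FALSE	FALSE	0	hydrogen	FALSE
1	alkane chain of length n	0	FALSE	FALSE	FALSE	FALSE	0	hydrogen	FALSE
2	alkane chain of length n	0	FALSE	FALSE	FALSE	FALSE	0	hydrogen	FALSE
3	alkane chain of length n	0	FALSE	FALSE	FALSE	FALSE	0	hydrogen	FALSE
4	alkane chain of length n	0	FALSE	FALSE	FALSE	FALSE	0	hydrogen	FALSE
5	alkane chain of length n	0	FALSE	FALSE	FALSE	FALSE	0	hydrogen	FALSE
6	alkane chain of length n	0	FALSE	FALSE	FALSE	FALSE	0	hydrogen	FALSE
7	alkane chain of length n	0	FALSE	FALSE	FALSE	FALSE	0	hydrogen	FALSE
8	alkane chain of length n	0	FALSE	FALSE	FALSE	FALSE	0	hydrogen	FALSE
9	alkane chain of length n	0	FALSE	FALSE	FALSE	FALSE	0	hydrogen	FALSE
&	punctuation	0	FALSE	FALSE	FALSE	FALSE	0	hydrogen	FALSE
-	punctuation	0	FALSE	FALSE	FALSE	FALSE	0	hydrogen	FALSE
 	punctuation	0	FALSE	FALSE	FALSE	FALSE	0	hydrogen	FALSE
/	punctuation	0	FALSE	FALSE	FALSE	FALSE	0	hydrogen	FALSE
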