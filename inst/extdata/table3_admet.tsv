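index	name	absorption	solubility	hepatotoxicity	ppb	role
1	Adenosine triphosphate	3	2	1	0	candidate
2	Chlorogenic acid	3	4	1	0	candidate
3	Cistanoside C	3	2	1	2	candidate
4	Forsythiaside	3	2	1	0	candidate
5	Isoacteoside	3	2	1	0	candidate
6	Isochlorogenic acid	3	4	1	0	candidate
7	Jionoside C	3	3	1	2	candidate
8	Jionoside D	3	2	1	2	candidate
9	Manninotriose	3	3	0	0	candidate
10	Methyl 4,6-di-O-galloyl-beta-D-glucopyranoside	3	2	1	0	candidate
11	Methyl 6-O-digalloyl-beta-D-glucopyranoside	3	2	1	0	candidate
12	Methyl 6-O-digalloyl-beta-D-glucopyranoside (II)	3	2	1	0	candidate
13	Methyl 3,3,6-tri-O-galloyl-beta-D-glucopyranoside	3	0	1	0	candidate
14	Raffinose	3	3	0	0	candidate
15	Rehmannioside A	3	4	1	0	candidate
16	Rehmannioside B	3	4	1	0	candidate
17	Rutin	3	1	1	2	candidate
18	Stachyose	3	1	0	0	candidate
NA	MTX	3	3	1	1	control
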