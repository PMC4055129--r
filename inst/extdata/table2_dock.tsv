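index	name	dock_dhfr	dock_ts	role
1	Adenosine triphosphate	226.6790	186.2170	candidate
2	Methyl 6-O-digalloyl-beta-D-glucopyranoside (II)	162.6260	154.1730	candidate
3	Methyl 4,6-di-O-galloyl-beta-D-glucopyranoside	153.7500	148.2880	candidate
4	Methyl 6-O-digalloyl-beta-D-glucopyranoside	151.7650	158.0350	candidate
5	Manninotriose	129.7870	114.6030	candidate
6	Forsythiaside	129.6030	27.9940	candidate
7	Isoacteoside	124.5900	30.6190	candidate
8	Rehmannioside B	119.9930	79.2920	candidate
9	Rehmannioside A	116.4330	71.3970	candidate
10	Raffinose	115.4940	134.2120	candidate
11	Cistanoside C	112.4270	NA	candidate
12	Methyl 3,3,6-tri-O-galloyl-beta-D-glucopyranoside	109.9470	20.7830	candidate
13	Stachyose	107.0940	8.5760	candidate
14	Chlorogenic acid	103.8080	NA	candidate
15	Jionoside D	103.5050	39.3430	candidate
16	Isochlorogenic acid	102.9470	NA	candidate
17	Jionoside C	102.3940	NA	candidate
18	Rutin	101.1310	78.816	candidate
NA	MTX	97.0960	NA	control
NA	MTX-PGs	NA	69.671	control
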