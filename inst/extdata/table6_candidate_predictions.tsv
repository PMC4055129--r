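name	mlr	bayesian	svm	comfa	ehda	eha
Adenosine triphosphate	6.4559	5.8145	8.7175	7.9640	7.8600	7.8350
Methyl 6-O-digalloyl-beta-D-glucopyranoside (II)	27.5044	5.1810	8.0157	6.9800	6.6030	5.5170
Methyl 4,6-di-O-galloyl-beta-D-glucopyranoside	27.7317	5.4868	8.4131	7.5490	6.5980	5.9300
Methyl 6-O-digalloyl-beta-D-glucopyranoside	26.7188	5.2477	7.8936	6.8980	6.6620	5.6840
Manninotriose	29.1034	5.1934	5.9247	7.6470	6.2450	5.3700
Forsythiaside	29.9821	5.3595	8.5713	7.7140	8.0830	7.8950
Isoacteoside	27.6319	6.3265	8.1255	7.6550	7.7990	7.5430
Rehmannioside B	26.7291	4.3032	7.3293	6.9990	6.8000	5.8300
Rehmannioside A	30.3632	4.4182	9.3324	6.7480	5.8070	4.6750
Raffinose	32.8592	5.1647	8.4766	6.9350	5.9620	4.2830
Cistanoside C	26.1802	5.7174	8.2029	7.6060	8.0200	7.9640
Methyl 3,3,6-tri-O-galloyl-beta-D-glucopyranoside	30.7405	6.0369	8.3193	6.7670	6.3240	6.6300
Stachyose	40.5491	5.9779	8.5055	7.4300	5.6830	4.4510
Chlorogenic acid	17.3951	4.2335	7.8897	7.8080	7.9640	7.7680
Jionoside D	26.0421	5.5238	8.2089	7.5080	7.4900	7.2820
Isochlorogenic acid	16.1484	4.4196	7.4839	7.1990	6.3590	6.4480
Jionoside C	23.7203	5.6640	8.2741	7.7600	7.0800	6.9110
Rutin	30.3096	5.6910	8.2465	6.5720	8.0190	7.6830
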