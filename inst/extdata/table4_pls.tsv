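model	onc	q2	r2	see	f	frac_s	frac_e	frac_h	frac_d	frac_a
CoMFA	7	0.5250	0.9630	0.2590	136.2760	0.7970	0.2030	NA	NA	NA
S	36	0.6350	0.9890	0.3040	19.6900	1.0000	0.0000	0.0000	0.0000	0.0000
E	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
H	2	0.6130	0.7760	0.5940	72.7070	0.0000	0.0000	1.0000	0.0000	0.0000
D	7	0.4180	0.7160	0.7130	13.3480	0.0000	0.0000	0.0000	1.0000	0.0000
A	1	0.0810	0.1600	1.1380	8.1640	0.0000	0.0000	0.0000	0.0000	1.0000
SE	37	0.6050	0.9890	0.3250	16.7260	0.9980	0.0200	0.0000	0.0000	0.0000
SH	2	0.5970	0.7790	0.5910	73.9120	0.3880	0.0000	0.6120	0.0000	0.0000
SD	36	0.6670	0.9890	0.3020	19.9580	0.6350	0.0000	0.0000	0.3650	0.0000
SA	30	0.7020	0.9890	0.2340	39.7820	0.7480	0.0000	0.0000	0.0000	0.2520
EH	7	0.6270	0.9540	0.2860	110.4680	0.0000	0.0500	0.9500	0.0000	0.0000
ED	7	0.4130	0.7090	0.7210	12.9020	0.0000	0.0180	0.0000	0.9820	0.0000
EA	2	0.0760	0.1830	1.1350	4.6860	0.0000	0.2000	0.0000	0.0000	0.8000
HD	2	0.5780	0.7940	0.5690	81.1680	0.0000	0.0000	0.7220	0.2780	0.0000
HA	2	0.5890	0.7910	0.5740	79.5410	0.0000	0.0000	0.7450	0.0000	0.2550
DA	9	0.4300	0.7290	0.7160	10.4430	0.0000	0.0000	0.0000	0.7800	0.2200
SHE	8	0.5850	0.9690	0.2400	139.5820	0.3570	0.0440	0.6000	0.0000	0.0000
SED	38	0.6500	0.9890	0.3490	14.1810	0.6340	0.0010	0.0000	0.3650	0.0000
SEA	31	0.7030	0.9880	0.2430	35.7980	0.7420	0.0110	0.0000	0.0000	0.2470
SHD	22	0.5780	0.9890	0.1830	89.3410	0.3070	0.0000	0.4490	0.2430	0.0000
SHA	2	0.5800	0.7950	0.5680	81.4850	0.3130	0.0000	0.4980	0.0000	0.1900
SDA	30	0.7170	0.9890	0.2320	40.3890	0.5640	0.0000	0.0000	0.2910	0.1450
EDA	11	0.4240	0.7380	0.7250	8.4650	0.0000	0.0200	0.0000	0.7640	0.2150
EHA	11	0.5770	0.9800	0.1990	148.9890	0.0000	0.0630	0.6910	0.0000	0.2460
HAD	2	0.5550	0.8020	0.5580	85.2150	0.0000	0.0000	0.6150	0.2080	0.1770
SEHD	23	0.5970	0.9890	0.1870	81.1730	0.2940	0.0230	0.4520	0.2310	0.0000
SEHA	23	0.5970	0.9800	0.1880	80.4080	0.3000	0.0420	0.4620	0.0000	0.1960
SEDA	31	0.7110	0.9890	0.2420	36.1870	0.5640	0.0050	0.0000	0.2840	0.1470
SHDA	5	0.5630	0.9290	0.3470	102.3970	0.2600	0.0000	0.3980	0.1920	0.1510
EHDA	12	0.6070	0.9820	0.1940	143.5670	0.0000	0.0500	0.5880	0.2040	0.1580
SEHDA	23	0.6120	0.9890	0.1880	80.3300	0.2690	0.0340	0.4020	0.1630	0.1330
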