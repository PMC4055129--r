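id	r1	r2	x	r3	pic50	set
1	CH3	CH3	CH2	H	4.71	train
2	CH3	CH3	CH2	4'-CH3	4.6091	train
3	CH3	CH3	CH2	4'-OCH3	4.2306	test
4	CH3	CH3	CH2	4'-F	4.6615	train
5	CH3	CH3	CH2	4'-Cl	4.5243	test
6	CH3	CH3	CH2	3',4'-diCl	4.8928	train
7	CH3	CH3	-O-CH2-	H	7.1612	test
8	CH3	C2H5	-O-CH2-	H	6.8097	train
9	H	c-Pr	-O-CH2-	H	6.2612	test
10	-(CH2)3-		-O-CH2-	H	6.8729	train
11	-(CH2)4-		-O-CH2-	H	6.762	train
12	-(CH2)5-		-O-CH2-	H	5.7471	train
13	-(CH2)6-		-O-CH2-	H	5.2733	train
14	-(CH2)4-		-O-CH2CH2-	H	7.5086	train
15	-(CH2)5-		-O-CH2CH2-	H	8.0458	train
16	-(CH2)4-		-O-(CH2)3-O-	H	7.699	train
17	-(CH2)5-		-O-(CH2)3-O-	H	7.4949	train
18	CH3	CH3	-O-(CH2)3-O-	H	8.2218	train
19	CH3	CH3	-O-(CH2)4-O-	H	7.5686	train
20	CH3	C2H5	-O-(CH2)3-O-	H	8.0969	train
21	H	c-Pr	-O-(CH2)3-O-	H	8.1549	train
22	-(CH2)4-		-O-(CH2)3-O-	H	8.699	train
23	-(CH2)4-		-O-(CH2)4-O-	H	7.3768	test
24	-(CH2)5-		-O-(CH2)3-O-	H	8.1549	train
25	-(CH2)5-		-O-(CH2)4-O-	H	6.8069	train
26	-(CH2)6-		-O-(CH2)3-O-	H	7.9586	train
27	-(CH2)5-		-O-(CH2)3-O-	F	7.8239	train
28	-(CH2)5-		-O-(CH2)3-O-	Cl	7.8539	train
29	-(CH2)5-		-O-(CH2)3-O-	NO2	7.8239	train
30	-(CH2)5-		-O-(CH2)3-O-	Me	7.7447	train
31	-(CH2)5-		-O-(CH2)3-O-	t-Bu	7.6576	train
32	-(CH2)5-		-O-(CH2)3-O-	OMe	8.2218	train
33	-(CH2)5-		-O-(CH2)3-O-	CN	8	test
34	-(CH2)5-		-O-(CH2)3-O-	COCH3	7.8861	train
35	-(CH2)5-		-O-(CH2)3-O-	SO2NH2	8.2218	train
36	-(CH2)4-		-O-(CH2)3-O-	F	8	test
37	-(CH2)4-		-O-(CH2)3-O-	Cl	8.1549	train
38	-(CH2)4-		-O-(CH2)3-O-	NO2	8.0969	train
39	-(CH2)4-		-O-(CH2)3-O-	Me	8	test
40	-(CH2)4-		-O-(CH2)3-O-	t-Bu	7.7696	train
41	-(CH2)4-		-O-(CH2)3-O-	OMe	7.9586	train
42	-(CH2)4-		-O-(CH2)3-O-	CN	8.0969	train
43	-(CH2)4-		-O-(CH2)3-O-	COCH3	8.0458	train
44	-(CH2)4-		-O-(CH2)3-N(Me)-	H	7.3872	test
45	-(CH2)4-		-O-(CH2)3-	H	7.4949	train
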