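id	set	experimental	comfa_pred	comfa_resid	ehda_pred	ehda_resid	eha_pred	eha_resid
1	train	4.710	4.652	0.0580	4.481	0.229	4.532	0.178
2	train	4.609	4.606	0.0031	4.635	-0.026	4.662	-0.053
3	test	4.231	4.576	-0.3454	4.333	-0.102	4.407	-0.176
4	train	4.662	5.027	-0.3655	4.698	-0.037	4.701	-0.039
5	test	4.524	4.571	-0.0467	4.807	-0.283	4.797	-0.273
6	train	4.893	4.476	0.4168	4.723	0.170	4.651	0.242
7	test	7.161	6.810	0.3512	7.287	-0.126	7.359	-0.198
8	train	6.810	6.529	0.2807	6.722	0.088	6.723	0.087
9	test	6.261	6.495	-0.2338	6.270	-0.009	6.240	0.021
10	train	6.873	6.648	0.2249	6.808	0.065	6.832	0.041
11	train	6.762	6.793	-0.0310	6.686	0.076	6.645	0.117
12	train	5.747	5.749	-0.0019	5.767	-0.020	5.705	0.042
13	train	5.273	5.346	-0.0727	5.245	0.028	5.279	-0.006
14	train	7.509	7.454	0.0546	7.494	0.015	7.522	-0.013
15	train	8.046	8.322	-0.2762	8.056	-0.010	8.052	-0.006
16	train	7.699	8.127	-0.4280	8.130	-0.431	8.110	-0.411
17	train	7.495	7.670	-0.1751	7.871	-0.376	7.820	-0.325
18	train	8.222	8.079	0.1428	8.130	0.092	8.105	0.117
19	train	7.569	7.561	0.0076	7.581	-0.012	7.609	-0.040
20	train	8.097	8.207	-0.1101	8.105	-0.008	8.240	-0.143
21	train	8.155	8.007	0.1479	8.242	-0.087	8.215	-0.060
22	train	8.699	8.127	0.5720	8.130	0.569	8.110	0.589
23	test	7.377	7.636	-0.2592	7.325	0.052	7.318	0.059
24	train	8.155	7.670	0.4849	7.871	0.284	7.820	0.335
25	train	6.807	7.113	-0.3061	6.902	-0.095	6.824	-0.017
26	train	7.959	7.987	-0.0284	7.887	0.072	7.975	-0.016
27	train	7.824	7.763	0.0609	7.981	-0.157	7.955	-0.131
28	train	7.854	7.839	0.0149	7.906	-0.052	7.850	0.004
29	train	7.824	7.843	-0.0191	7.824	0.000	7.827	-0.003
30	train	7.745	7.914	-0.1693	7.736	0.009	7.733	0.012
31	train	7.658	8.069	-0.4114	7.665	-0.007	7.654	0.004
32	train	8.222	8.005	0.2168	7.848	0.374	7.814	0.408
33	test	8.000	8.100	-0.1000	7.978	0.022	8.010	-0.010
34	train	7.886	7.455	0.4311	7.947	-0.061	7.811	0.075
35	train	8.222	7.981	0.2408	8.208	0.014	8.237	-0.015
36	test	8.000	8.173	-0.1730	8.130	-0.130	8.139	-0.139
37	train	8.155	8.180	-0.0251	8.170	-0.015	8.187	-0.032
38	train	8.097	8.122	-0.0251	8.097	0.000	8.097	0.000
39	test	8.000	7.990	0.0100	8.007	-0.007	8.054	-0.054
40	train	7.770	7.683	0.0866	7.832	-0.062	7.697	0.073
41	train	7.959	8.223	-0.2644	7.883	0.076	7.907	0.052
42	train	8.097	7.974	0.1229	8.040	0.057	8.150	-0.053
43	train	8.046	7.996	0.0498	8.052	-0.006	8.061	-0.015
44	test	7.387	7.542	-0.1548	7.567	-0.180	7.590	-0.203
45	train	7.495	7.449	0.0459	7.484	0.011	7.516	-0.021
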