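no	tf	target	p_dcg	cor1	cor2	type	star	retained
1	AHR	TLE4	6.77e-23	0.94	0.14	0	target	TRUE
2	ZEB1	ATP12A	3.56e-73	-0.54	0.95	1	target	TRUE
3	FOXL1	CBX6	0.014521	0.95	0.13	0	tf	TRUE
4	CEBPB	PLEKHM1	0.000574	0.18	0.94	0	target	TRUE
5	CREB1	TGM1	0.001644	0.87	0.05	0	target	TRUE
6	CREB1	CROCCP2	5.02e-09	0.92	0.07	0	target	TRUE
7	PATZ1	DYRK2	2.79e-16	-0.88	-0.02	0	target	TRUE
8	FOS	FEZ2	0.000107	0.03	0.96	0	target	TRUE
9	MYCN	FLRT2	9.32e-05	0.29	-0.98	1	target	TRUE
10	FOSL1	HIVEP3	6.37e-06	0.94	0.02	0	tf	TRUE
11	FOSL1	DSCAML1	6.37e-06	0.91	0.16	0	tf	TRUE
12	GATA1	COL19A1	9.63e-10	0.12	0.93	0	target	TRUE
13	JUN	GRIA4	4.30e-10	-0.60	0.97	1	tf	TRUE
14	SRF	HCG18	1.23e-18	-0.91	-0.14	0	tf	TRUE
15	HLF	LRRTM4	0.022779	0.92	0.18	0	tf	TRUE
16	E2F5	ID1	0.008474	-0.88	-0.11	0	target	TRUE
17	JUN	ZNF830	4.30e-10	-0.09	-0.93	0	tf	TRUE
18	JUN	SPOP	4.30e-10	-0.11	-0.95	0	tf	TRUE
19	JUN	GAK	4.30e-10	-0.43	0.96	1	tf	TRUE
20	JUN	CHURC1	4.30e-10	0.51	-0.95	1	tf	TRUE
21	PAX5	KCTD7	1.14e-05	0.97	-0.54	1	target	TRUE
22	JUN	KLF6	4.30e-10	0.89	0.12	0	tf	TRUE
23	MZF1	MID1	0.006234	0.96	-0.28	1	target	TRUE
24	MZF1	EPHB2	0.012953	-0.93	-0.13	0	target	TRUE
25	SRF	NDUFA1	1.23e-18	0.88	0.12	0	tf	TRUE
26	NFYA	PANK2	5.37e-05	-0.13	0.97	1	target	TRUE
27	MRPL36	NR4A1	1.34e-08	0.88	-0.94	1	target	TRUE
28	NF1	NUPL2	1.86e-35	0.91	0.10	0	target	TRUE
29	ZEB1	OTOF	2.62e-07	0.06	-0.96	1	target	TRUE
30	HAND1	PITX2	5.83e-06	-0.90	-0.01	0	target	TRUE
31	PLAU	LNP1	2.00e-19	-0.01	-0.92	0	target	TRUE
32	PSG1	YRDC	6.27e-11	0.11	0.93	0	target	TRUE
33	RFX1	SNORA21	3.87e-38	0.98	-0.05	1	target	TRUE
34	RFX1	LOC283481	3.34e-55	0.96	-0.33	1	target	TRUE
35	SOX9	FLAD1	8.34e-09	-0.92	-0.10	0	tf	TRUE
36	SREBF1	PHOX2B	0.002661	0.89	0.06	0	target	TRUE
37	SRF	C4orf7	1.23e-18	-0.96	0.74	1	tf	TRUE
38	SRF	SHMT1	1.23e-18	-0.92	-0.12	0	tf	TRUE
39	STAT5B	TRAK2	1.42e-06	0.45	-0.95	1	target	TRUE
40	TCF3	C11orf61	0.003455	-0.87	-0.10	0	target	TRUE
41	TFAP4	BSCL2	3.03e-16	-0.06	-0.94	0	tf	TRUE
42	TLX2	C3orf70	6.53e-06	0.03	-0.97	1	both	FALSE
43	FOXL1	TOB1	0.014521	-0.88	-0.11	0	tf	TRUE
44	TLX2	TSPAN8	6.53e-06	-0.94	-0.11	0	tf	FALSE
45	CREB1	VPS26A	6.76e-05	0.92	0.05	0	target	TRUE
46	SRF	VWA3A	1.23e-18	-0.89	-0.08	0	tf	TRUE
47	YY1	ZNF518A	1.93e-119	0.90	0.04	0	target	TRUE
48	POU2F1	ZNF518A	1.93e-119	0.98	-0.15	1	target	TRUE
49	ZSCAN1	KRT13	4.80e-10	0.89	0.15	0	target	TRUE
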