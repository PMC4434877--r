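no	tf	target	p_dcg	cor1	cor2	type	star	retained
1	PATZ1	ADAM17	0.018596	-0.71	0.97	1	tf	TRUE
2	PATZ1	CALM3	0.018596	0.03	0.94	0	tf	TRUE
3	PATZ1	CIB1	0.018596	0.03	0.93	0	tf	TRUE
4	TP53	FUS	0.001496	-0.47	0.97	1	target	FALSE
5	PATZ1	LOC100130776	0.018596	0.54	-0.97	1	tf	TRUE
6	CBFB	MACROD2	0.029467	-0.53	0.97	1	target	TRUE
7	PATZ1	NLGN2	0.018596	-0.07	-0.94	0	tf	TRUE
8	PATZ1	SECISBP2L	0.018596	-0.68	0.97	1	tf	TRUE
9	PATZ1	POLD4	0.018596	-0.18	0.97	1	tf	TRUE
10	PATZ1	PTMA	0.018596	-0.37	0.97	1	tf	TRUE
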