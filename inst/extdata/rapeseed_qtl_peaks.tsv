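trait	qtl	chrom	peak_pos	p_value
FT	qFT.A02	A02	31103911	6.31e-08
FT	qFT.A04	A04	22846166	6.33e-09
FT	qFT.A06	A06	47559072	5.57e-11
FT	qFT.A07	A07	16408859	1.25e-11
FT	qFT.A09	A09	48835744	4.62e-10
FT	qFT.C06	C06	7993765	1.51e-08
FT	qFT.C08	C08	44432255	5.79e-14
FT	qFT.C09	C09	64831981	4.33e-09
OC	qOC.A01	A01	23099126	2.33e-07
OC	qOC.A03	A03	22570735	8.40e-07
OC	qOC.A05	A05	41113713	7.35e-08
OC	qOC.C01	C01	6005735	1.50e-07
OC	qOC.C05	C05	54016444	1.44e-08
OC	qOC.C09	C09	44501778	7.04e-07
SL	qSL.A09	A09	57148997	1.96e-10
SL	qSL.C03	C03	17931133	2.76e-07
SN	qSN.A04	A04	5536474	6.59e-07
SN	qSN.A06	A06	5679650	3.70e-07
SN	qSN.A09	A09	13303680	4.15e-07
SN	qSN.C09	C09	63093434	7.34e-07
TSW	qTSW.A09	A09	57502874	3.27e-08
TSW	qTSW.C08	C08	46461951	2.78e-07
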