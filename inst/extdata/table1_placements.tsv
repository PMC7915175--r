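bac_id	gene	chromosome_of_origin	arm	species	target_chromosome
52G10	lamb1	2	1	SSE	2
52G10	ssbp1	2	1	SSE	2
52G10	creb3l2	2	1	SSE	2
52G10	dgki	2	1	SSE	2
52G10	calu	2	1	SSE	2
52G10	opn1sw	2	1	SSE	2
52G10	tnpo3	2	1	SSE	2
52G10	irf5	2	1	SSE	2
52G10	atp6v1f	2	1	SSE	2
52G10	dennd6b	2	1	SSE	2
52G10	gcc1	2	1	SSE	2
52G10	arf5	2	1	SSE	2
52G10	lta4h	2	1	SSE	2
52G10	mical3a	2	1	SSE	2
6P22	mri1	2	1	SSE	2
6P22	rfx1	2	1	SSE	2
6P22	dcaf15	2	1	SSE	2
6P22	khsrp	2	1	SSE	2
6P22	slc25a24	2	1	SSE	2
6P22	rgs5	2	1	SSE	2
6P22	c19orf53	2	1	SSE	2
6P22	gng10	2	1	SSE	2
6P22	ssx2ip	2	1	SSE	2
6P22	nanos3	2	1	SSE	2
6P22	cc2d1a	2	1	SSE	2
6P22	umod	2	1	SSE	2
6P22	slc26a11	2	1	SSE	2
6P22	sgsh	2	1	SSE	2
6P22	npb	2	1	SSE	2
6P22	sirt7	2	1	SSE	2
6P22	pcyt2	2	1	SSE	2
6P22	gnao1	2	1	SSE	2
6P22	mafg	2	1	SSE	2
6P22	map2k5	2	1	SSE	2
6P22	skor1b	2	1	SSE	2
9E8	thrβ	2	1	SSE	2
9E8	nr1d2	2	1	SSE	2
9E8	ube2e2	2	1	SSE	2
60P19	trim39	2	1	SSE	2
60P19	c1qtnf3	2	1	SSE	2
60P19	casq1b	2	1	SSE	2
60P19	pea15	2	1	SSE	2
60P19	mrpl48	2	1	SSE	2
60P19	supt16h	2	1	SSE	2
60P19	trim25	2	1	SSE	2
60P19	fam234a	2	1	SSE	2
60P19	mrc2	2	1	SSE	2
46C5	ndrg2	2	1	SSE	2
46C5	hnrnpc	2	1	SSE	2
46C5	fhod1	2	1	SSE	2
46C5	klhl33	2	1	SSE	2
46C5	c1ql2	2	1	SSE	2
46C5	parp14	2	1	SSE	2
46C5	mrc1	2	1	SSE	2
46C5	slc12a3	2	1	SSE	2
46C5	ltb4r	2	1	SSE	2
46C5	myadm	2	1	SSE	2
46C5	arhgef11a	2	1	SSE	2
46C5	apol6	2	1	SSE	2
36I3	chd3	2	1	SSE	2
36I3	tnfsf12	2	1	SSE	2
4D15	ppme1	2	1	SSE	2
4D15	rnf150	2	1	SSE	2
4D15	inpp4b	2	1	SSE	2
4D15	hmgb2	2	1	SSE	2
4D15	dlg4	2	1	SSE	2
38N10	tmbim4	2	2	SSE	2
38N10	b2m	2	2	SSE	2
38N10	gdi2	2	2	SSE	2
38N10	asb13	2	2	SSE	2
38N10	net1	2	2	SSE	2
38N10	hspa14	2	2	SSE	2
38N10	manf	2	2	SSE	2
38N10	irak3	2	2	SSE	2
38N10	prl	2	2	SSE	2
3F15	slc18a3a	2	2	SSE	2
3F15	rgr	2	2	SSE	2
3F15	lrit1	2	2	SSE	2
21O23	fabp2	2	2	SSE	2
21O23	dmrt4	2	2	SSE	2
21O23	adcyap1r1	2	2	SSE	2
19L16	kiaa1324	2	2	SSE	2
19L16	c1orf194	2	2	SSE	2
19L16	smc5	2	2	SSE	2
19L16	fam107b	2	2	SSE	2
12N15	tuba1c	4	p	SSE	4
12N15	taar13c	4	p	SSE	4
12N15	atp1b1b	4	p	SSE	4
12N15	ube3a	4	p	SSE	4
12N15	gpd2	4	p	SSE	4
12N15	hsf2bp	4	p	SSE	4
12N15	cnga3	4	p	SSE	4
12N15	ddx4	4	p	SSE	4
12N15	ccdc14	4	p	SSE	4
12N15	ankrd10	4	p	SSE	4
12N15	dpp10	4	p	SSE	4
12N15	nr4a2	4	p	SSE	4
3C15	pde11a	4	q	SSE	4
3C15	cycsb	4	q	SSE	4
3C15	osbpl6	4	q	SSE	4
46B2	uggt2	4	q	SSE	4
46B2	dnajc3	4	q	SSE	4
46B2	cldn10	4	q	SSE	4
46B2	abcc4	4	q	SSE	4
46B2	dct	4	q	SSE	4
46B2	sox21	4	q	SSE	4
46B2	gpc6	4	q	SSE	4
30J4	nlrc3	4	q	SSE	4
30J4	wdr90	4	q	SSE	4
30J4	rhot2	4	q	SSE	4
30J4	H1.0B	4	q	SSE	4
30J4	rhbdl1	4	q	SSE	4
30J4	wdr24	4	q	SSE	4
30J4	anks3	4	q	SSE	4
30J4	c8orf33	4	q	SSE	4
30J4	H3.3	4	q	SSE	4
30J4	gcgr	4	q	SSE	4
30J4	pcdh8	4	q	SSE	4
30J4	ednrb	4	q	SSE	4
30J4	cog3	4	q	SSE	4
30J4	mid1	4	q	SSE	4
30J4	arhgap6	4	q	SSE	4
30J4	tlr7	4	q	SSE	4
30J4	tlr8	4	q	SSE	4
30J4	tyb12	4	q	SSE	4
30J4	egfl6	4	q	SSE	4
12D24	igsf3	4	q	SSE	4
12D24	rpe	4	q	SSE	4
12D24	ackr3	4	q	SSE	4
12D24	nqo1	4	q	SSE	4
12D24	nhlh2	4	q	SSE	4
12D24	vangl1	4	q	SSE	4
12D24	casq2	4	q	SSE	4
12D24	kcne2	4	q	SSE	4
12D24	slc5a3	4	q	SSE	4
12D24	dop1b	4	q	SSE	4
12D24	morc3	4	q	SSE	4
12D24	ptprn	4	q	SSE	4
8A23	hibch	4	q	SSE	4
8A23	c2orf88	4	q	SSE	4
8A23	mstn	4	q	SSE	4
8A23	pms1	4	q	SSE	4
8A23	ormdl1	4	q	SSE	4
8A23	adat3	4	q	SSE	4
8A23	alkbh6	4	q	SSE	4
8A23	osgepl1	4	q	SSE	4
8A23	fkbp7	4	q	SSE	4
8A23	gls	4	q	SSE	4
46P22	zfpm1	4	q	SSE	4
46P22	trhr2	4	q	SSE	4
36J2	crygs	4	q	SSE	4
36H3	ccdc141	4	q	SSE	4
36H3	tchh	4	q	SSE	4
36H3	ttn	4	q	SSE	4
36H2	ccdc141	4	q	SSE	4
36H2	tchh	4	q	SSE	4
36H2	ttn	4	q	SSE	4
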