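locus	scaffold	motif	repeat_units	size_min	size_max	n_alleles	tm	n_genotyped	fluor	panel	hwe_deviant_pops	ambiguous_peaks
wft3-S01	KL023705	AAT	12	162	246	16	56	47	HEX	MP	1	TRUE
wft3-S03	KL023701	AGC	12	135	188	8	56	45	HEX		0	FALSE
wft3-S06	KL023747	AGC	8	142	159	5	56	46	HEX		0	FALSE
wft3-S08	KL023707	ACG	8	155	173	5	56	47	HEX	SS	0	FALSE
wft4-S09	KL023695	AGGC	7	165	185	5	56	47	HEX	SS	1	FALSE
wft4-S13	KL023711	AACC	16	157	184	4	56	47	HEX	SS	0	FALSE
wft3-S14	KL023717	AAG	22	178	222	10	56	47	HEX	SS	0	FALSE
wft4-S16	KL023774	ACAG	14	190	223	8	56	43	HEX		0	FALSE
wft4-S17	KL023720	ACAG	20	99	249	10	56	46	HEX		0	FALSE
wft3-S20	KL023696	AGC	17	204	271	6	56	46	HEX		0	FALSE
wft3-S21	KL023772	AAT	15	243	284	11	56	45	FAM	MP	1	FALSE
wft4-S22	KL023713	AGAT	9	240	300	13	56	46	FAM	SNI	1	FALSE
wft4-S26	KL023743	ACAG	17	220	321	11	56	44	FAM	MP	1	FALSE
wft3-S27	KL023766	ACC	13	224	263	10	56	44	FAM	SNI	1	FALSE
wft3-S28	KL023710	ACT	10	236	253	10	56	47	FAM	SNI	0	FALSE
wft4-S29	KL023712	ACGC	11	233	272	9	56	41	FAM		0	FALSE
wft4-S30	KL023745	ACGG	11	217	336	11	56	47	FAM	SNI	1	FALSE
wft4-S31	KL023716	ACTC	13	209	261	11	56	41	FAM	MP	2	FALSE
wft4-S32	KL023729	ACAG	16	212	359	17	56	45	FAM	MP	1	FALSE
wft3-S33	KL023736	AGC	10	238	255	10	56	47	FAM	SNI	0	FALSE
wft4-S34	KL023718	AGAT	13	234	273	9	56	46	ROX		0	FALSE
wft4-S36	KL023722	AAAG	10	275	293	6	56	46	ROX		0	FALSE
wft3-S43	KL023742	AGC	20	258	299	11	56	47	ROX	MP,SS	0	FALSE
wft4-S45	KL023755	ACAG	8	296	320	6	56	47	ROX	SS	0	FALSE
wft4-S50	KL023714	ATCC	13	303	351	7	56	47	ROX	SS	0	FALSE
wft4-S52	KL023739	AAAC	11	312	366	10	56	39	ROX	SNI	0	FALSE
wft3-S53	KL023752	AAC	17	299	357	11	56	47	ROX	SNI	1	FALSE
wft4-S57	KL023777	AGAT	23	338	416	13	56	43	ROX	MP	2	FALSE
wft4-S58	KL023694	AGAT	15	338	394	12	56	47	ROX	MP,SS	0	FALSE
wft3-S60	KL023732	AGC	8	358	383	8	56	47	ROX	SNI	0	FALSE
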