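functional_class	gene	hgvs_p	patient_id	sex	age_recruit	age_onset	drug_group	febrile_seizure	classification	etiology	pathogenic	two_hit
ion_channel	CHRNA4	p.Arg345Cys	DK085	M	26	12	DS	N	focal	Non-lesional	TRUE	FALSE
ion_channel	GABRG2	p.Ser8Arg	JN086	M	22	4	DR	N	focal	Tumor	FALSE	FALSE
ion_channel	GABRG2	p.Ser8Arg	JN167	M	68	10	DR	Y	focal	Non-lesional	FALSE	FALSE
ion_channel	HCN1	p.Ser100Ala	SC009	M	24	15	DS	N	focal	Non-lesional	FALSE	FALSE
ion_channel	KCNB1	p.Ile463Thr	JN134	F	52	29	DS	Y	focal	FCD	FALSE	FALSE
ion_channel	KCNT1	p.Glu892Lys	SU059	M	25	20	DR	N	focal	Non-lesional	FALSE	TRUE
ion_channel	SCN1A	p.Thr398Met	JN129	F	43	29	DR	N	focal	HS	FALSE	FALSE
ion_channel	SCN1A	p.Val971Ile	JN168	M	30	1	DR	N	focal	Non-lesional	FALSE	FALSE
ion_channel	SCN1A	p.Val971Ile	KG012	M	43	38	DR	N	focal	Trauma	FALSE	FALSE
ion_channel	SCN1A	p.Arg1575Cys	JN046	F	54	16	DS	N	focal	Non-lesional	FALSE	FALSE
ion_channel	SCN1A	p.Arg1575Cys	JN166	F	43	29	DS	N	focal	Non-lesional	FALSE	FALSE
ion_channel	SCN9A	p.Asn641Ser	DK098	F	35	12	DR	NA	focal	HS	FALSE	FALSE
mtor	DEPDC5	p.Arg587X	DK023	F	26	19	DS	N	focal	Non-lesional	TRUE	FALSE
mtor	DEPDC5	p.Pro1031His	SU059	M	25	20	DR	N	focal	Non-lesional	FALSE	TRUE
mtor	DEPDC5	p.Pro1031His	JN114	M	38	11	DS	N	focal	Non-lesional	FALSE	FALSE
mtor	TSC1	p.Ser829Arg	SU036	M	40	1	DR	N	focal	FCD	FALSE	FALSE
mtor	TSC1	p.Ser829Arg	KH015	F	45	37	DS	N	focal	HS	FALSE	FALSE
mtor	TSC1	p.Thr899Ser	SU023	M	33	21	DR	N	focal	FCD	FALSE	TRUE
mtor	TSC1	p.Thr899Ser	JN036	M	51	41	DS	Y	focal	Trauma	FALSE	TRUE
mtor	TSC1	p.Pro1143Leu	JN224	F	65	55	DS	N	focal	Encephalitis	FALSE	TRUE
mtor	TSC2	p.Val963Met	KH016	F	42	34	DR	N	focal	HS	FALSE	FALSE
mtor	TSC2	p.Leu1027Pro	JN056	M	37	7	DR	N	focal	TS	FALSE	TRUE
mtor	TSC2	p.Glu1476Gln	JN051	M	49	28	DR	N	focal	HS	TRUE	FALSE
mtor	TSC2	p.Glu1490Gly	EW001	F	64	8	DR	N	focal	HS	FALSE	FALSE
mtor	TSC2	p.Arg1529Gln	JN006	F	31	18	DS	N	focal	Non-lesional	FALSE	FALSE
adhesion	ADGRV1	p.His1859Arg	JN036	M	51	41	DS	Y	focal	Trauma	FALSE	TRUE
adhesion	ADGRV1	p.His1859Arg	JN023	F	25	5	DR	Y	focal	HS	FALSE	FALSE
adhesion	ADGRV1	p.His1859Arg	DK066	F	56	46	DS	N	generalized	Non-lesional	FALSE	FALSE
adhesion	CNTNAP2	p.Ile172Thr	SU023	M	33	21	DR	N	focal	FCD	FALSE	TRUE
adhesion	CNTNAP2	p.Arg1288Cys	JN041	M	38	17	DR	N	focal	Non-lesional	FALSE	FALSE
signal_transduction	EFHC1	p.Arg294Cys	JN172	M	36	32	DS	Y	focal	Trauma	FALSE	FALSE
signal_transduction	PRICKLE1	p.Ala541Ser	JN072	M	60	33	DR	Y	focal	Non-lesional	FALSE	FALSE
signal_transduction	PRICKLE1	p.Ala541Ser	JN224	F	65	55	DS	N	focal	Encephalitis	FALSE	TRUE
signal_transduction	PRICKLE1	p.Ala541Ser	YC009	M	34	2	DR	Y	focal	Non-lesional	FALSE	FALSE
ecm	RELN	p.Lys751Thr	SU018	F	44	7	DR	N	focal	Non-lesional	FALSE	FALSE
ecm	RELN	p.Thr1904Met	DK021	F	44	25	DR	N	focal	HS	FALSE	FALSE
ecm	RELN	p.Thr1904Met	JN056	M	37	7	DR	N	focal	TS	FALSE	TRUE
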