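gene	chrom	pos	hgvs_p	or_value	ci_low	ci_high	criteria	interpretation
ADGRV1	chr5	89977183	p.His1859Arg	11.7	3.6	37.6	PS4, PM6, PP3, PP5	Likely pathogenic
CHRNA4	chr20	61981730	p.Arg345Cys	NA	NA	NA	PS1, PS3, PM2, PM6, PP3	Pathogenic
CNTNAP2	chr7	146741111	p.Ile172Thr	35.7	4.3	290.5	PS4, PM6, PP3, PP5	Likely pathogenic
CNTNAP2	chr7	148112574	p.Arg1288Cys	83.3	8.6	802.2	PS4, PM6, PP3, PP5	Likely pathogenic
DEPDC5	chr22	32215100	p.Arg587X	NA	NA	NA	PVS1, PS3, PM2, PM6, PP3	Pathogenic
DEPDC5	chr22	32242890	p.Pro1031His	7	1.7	28.7	PS4, PM6, PP3	Likely pathogenic
EFHC1	chr6	52319049	p.Arg294Cys	125.2	11.3	1382.9	PS4, PM5, PP3, PP5	Likely pathogenic
GABRG2	chr5	161495029	p.Ser8Arg	250.6	35.2	1782.6	PS4, PM6, PP3, PP5	Likely pathogenic
HCN1	chr5	45695898	p.Ser100Ala	235.5	14.7	3770.7	PS4, PM5, PM6, PP3	Likely pathogenic
KCNB1	chr20	47990709	p.Ile463Thr	14.7	1.9	110.8	PS4, PM6, PP3	Likely pathogenic
KCNT1	chr9	138670613	p.Glu892Lys	24.9	3.1	194.6	PS4, PM6, PP3, PP5	Likely pathogenic
PRICKLE1	chr12	42858215	p.Ala541Ser	376.9	62.8	2260.6	PS4, PM6, PP3, PP5	Likely pathogenic
RELN	chr7	103197510	p.Thr1904Met	23.6	5.5	100.9	PS4, PM6, PP3, PP5	Likely pathogenic
RELN	chr7	103276733	p.Lys751Thr	9.6	1.3	71.1	PS4, PM6, PP3, PP5	Likely pathogenic
SCN1A	chr2	166850785	p.Arg1575Cys	55.3	11.9	256.8	PS4, PM6, PP3, PP5	Likely pathogenic
SCN1A	chr2	166903464	p.Thr398Met	250.3	15.6	4007.8	PS4, PM6, PP3	Likely pathogenic
SCN1A	chr2	166894321	p.Val971Ile	55.3	11.9	256.7	PS4, PM6, PP3, PP5	Likely pathogenic
SCN9A	chr2	167141015	p.Asn641Ser	123.3	11.2	1362.3	PS4, PM5, PM6, PP3	Likely pathogenic
TSC1	chr9	135771689	p.Pro1143Leu	83.4	8.7	803.3	PS4, PM6, PP3, PP5	Likely pathogenic
TSC1	chr9	135772927	p.Thr899Ser	41.8	9.3	187.3	PS4, PM6, PP3, PP5	Likely pathogenic
TSC1	chr9	135776993	p.Ser829Arg	62.4	13.2	294.6	PS4, PM6, PP3, PP5	Likely pathogenic
TSC2	chr16	2134649	p.Glu1476Gln	62.1	6.9	556.7	PS4, PM5, PM6, PP3, PP5	Pathogenic
TSC2	chr16	2135247	p.Arg1529Gln	13.3	1.8	100.2	PS4, PM6, PP3, PP5	Likely pathogenic
TSC2	chr16	2127648	p.Val963Met	41.7	5	347.2	PS4, PM6, PP3, PP5	Likely pathogenic
TSC2	chr16	2129146	p.Leu1027Pro	NA	NA	NA	PM2, PM6, PP3, PP5	Likely pathogenic
TSC2	chr16	2134692	p.Glu1490Gly	14.5	1.9	108.7	PS4, PM6, PP3, PP5	Likely pathogenic
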