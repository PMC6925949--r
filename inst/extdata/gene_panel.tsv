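gene	category	inheritance	functional_class	alias
AARS	epilepsy_gene	unknown	other	
ADRA2B	epilepsy_gene	unknown	other	
ADSL	epilepsy_gene	unknown	other	
ALDH7A1	epilepsy_gene	recessive	other	
ALG13	epilepsy_gene	unknown	other	
ARV1	epilepsy_gene	unknown	other	
ATP6AP2	epilepsy_gene	unknown	other	
CACNA1A	epilepsy_gene	unknown	ion_channel	
CACNA1H	epilepsy_gene	unknown	ion_channel	
CACNB4	epilepsy_gene	unknown	ion_channel	
CASR	epilepsy_gene	unknown	other	
CDKL5	epilepsy_gene	x_linked	other	
CERS1	epilepsy_gene	unknown	other	
CHD2	epilepsy_gene	unknown	other	
CHRNA2	epilepsy_gene	unknown	ion_channel	
CHRNA4	epilepsy_gene	dominant	ion_channel	
CHRNB2	epilepsy_gene	unknown	ion_channel	
CLCN2	epilepsy_gene	unknown	ion_channel	
CLN3	epilepsy_gene	recessive	other	
CLN5	epilepsy_gene	unknown	other	
CLN6	epilepsy_gene	unknown	other	
CLN8	epilepsy_gene	recessive	other	
CNTN2	epilepsy_gene	unknown	adhesion	
CPA6	epilepsy_gene	unknown	other	
CSTB	epilepsy_gene	unknown	other	
CTSD	epilepsy_gene	unknown	other	
DEPDC5	epilepsy_gene	dominant	mtor	
DNM1	epilepsy_gene	unknown	other	
DOCK7	epilepsy_gene	unknown	other	
EEF1A2	epilepsy_gene	unknown	other	
EFHC1	epilepsy_gene	dominant	signal_transduction	
EPM2A	epilepsy_gene	unknown	other	
FGF12	epilepsy_gene	unknown	signal_transduction	
FOXG1	epilepsy_gene	unknown	other	
FRRS1L	epilepsy_gene	unknown	other	
GABRA1	epilepsy_gene	unknown	ion_channel	
GABRB1	epilepsy_gene	unknown	ion_channel	
GABRB3	epilepsy_gene	unknown	ion_channel	
GABRD	epilepsy_gene	unknown	ion_channel	
GABRG2	epilepsy_gene	dominant	ion_channel	
GAL	epilepsy_gene	unknown	other	
GAMT	epilepsy_gene	unknown	other	
GATM	epilepsy_gene	unknown	other	
GNAO1	epilepsy_gene	unknown	signal_transduction	
GOSR2	epilepsy_gene	unknown	other	
GPR98	epilepsy_gene	dominant	adhesion	ADGRV1
GRIN2A	epilepsy_gene	dominant	ion_channel	
GRIN2B	epilepsy_gene	unknown	ion_channel	
GRIN2D	epilepsy_gene	unknown	ion_channel	
GUF1	epilepsy_gene	unknown	other	
HCN1	epilepsy_gene	dominant	ion_channel	
ITPA	epilepsy_gene	unknown	other	
KCNA2	epilepsy_gene	unknown	ion_channel	
KCNB1	epilepsy_gene	dominant	ion_channel	
KCNC1	epilepsy_gene	unknown	ion_channel	
KCNMA1	epilepsy_gene	unknown	ion_channel	
KCNQ2	epilepsy_gene	dominant	ion_channel	
KCNQ3	epilepsy_gene	unknown	ion_channel	
KCNT1	epilepsy_gene	dominant	ion_channel	
KCTD7	epilepsy_gene	unknown	other	
LGI1	epilepsy_gene	dominant	other	
LMNB2	epilepsy_gene	unknown	other	
MFSD8	epilepsy_gene	recessive	other	
NECAP1	epilepsy_gene	unknown	other	
NHLRC1	epilepsy_gene	recessive	other	
NPRL2	epilepsy_gene	unknown	mtor	
NPRL3	epilepsy_gene	unknown	mtor	
NRXN1	epilepsy_gene	recessive	adhesion	
PCDH19	epilepsy_gene	x_linked	adhesion	
PLCB1	epilepsy_gene	unknown	signal_transduction	
PNPO	epilepsy_gene	unknown	other	
POLG	epilepsy_gene	recessive	other	
PPT1	epilepsy_gene	unknown	other	
PRDM8	epilepsy_gene	unknown	other	
PRICKLE1	epilepsy_gene	dominant	signal_transduction	
PRIMA1	epilepsy_gene	unknown	other	
PRRT2	epilepsy_gene	dominant	other	
SCARB2	epilepsy_gene	unknown	other	
SCN1A	epilepsy_gene	dominant	ion_channel	
SCN1B	epilepsy_gene	unknown	ion_channel	
SCN2A	epilepsy_gene	dominant	ion_channel	
SCN8A	epilepsy_gene	dominant	ion_channel	
SCN9A	epilepsy_gene	dominant	ion_channel	
SIK1	epilepsy_gene	unknown	other	
SLC12A5	epilepsy_gene	unknown	ion_channel	
SLC13A5	epilepsy_gene	unknown	other	
SLC1A2	epilepsy_gene	unknown	ion_channel	
SLC25A12	epilepsy_gene	unknown	other	
SLC25A22	epilepsy_gene	unknown	other	
SLC2A1	epilepsy_gene	unknown	ion_channel	
SLC6A1	epilepsy_gene	unknown	ion_channel	
SLC9A6	epilepsy_gene	x_linked	other	
SPTAN1	epilepsy_gene	unknown	other	
ST3GAL3	epilepsy_gene	unknown	other	
ST3GAL5	epilepsy_gene	unknown	other	
STX1B	epilepsy_gene	unknown	other	
STXBP1	epilepsy_gene	unknown	signal_transduction	
SZT2	epilepsy_gene	unknown	other	
TBC1D24	epilepsy_gene	recessive	other	
TCF4	epilepsy_gene	unknown	other	
TPP1	epilepsy_gene	unknown	other	
UBA5	epilepsy_gene	unknown	other	
UBE3A	epilepsy_gene	unknown	other	
WWOX	epilepsy_gene	recessive	other	
ZEB2	epilepsy_gene	unknown	other	
ANKLE2	neurodevelopment_gene	unknown	other	
AMPD2	neurodevelopment_gene	unknown	other	
ARFGEF2	neurodevelopment_gene	unknown	other	
ARX	neurodevelopment_gene	x_linked	other	
ASPM	neurodevelopment_gene	recessive	other	
ATN1	neurodevelopment_gene	unknown	other	
CASK	neurodevelopment_gene	x_linked	other	
CCDC88C	neurodevelopment_gene	recessive	other	
CDK5	neurodevelopment_gene	unknown	other	
CENPE	neurodevelopment_gene	unknown	other	
CENPJ	neurodevelopment_gene	recessive	other	
CLP1	neurodevelopment_gene	unknown	other	
CNTNAP2	neurodevelopment_gene	dominant	adhesion	
COL4A2	neurodevelopment_gene	unknown	ecm	
DCX	neurodevelopment_gene	x_linked	other	
DIAPH1	neurodevelopment_gene	unknown	other	
EMX2	neurodevelopment_gene	unknown	other	
ERMARD	neurodevelopment_gene	unknown	other	
EXOSC3	neurodevelopment_gene	unknown	other	
FIG4	neurodevelopment_gene	unknown	other	
FLNA	neurodevelopment_gene	x_linked	other	
GPR56	neurodevelopment_gene	recessive	adhesion	ADGRG1
HERC1	neurodevelopment_gene	unknown	other	
IER3IP1	neurodevelopment_gene	unknown	other	
KATNB1	neurodevelopment_gene	unknown	other	
KIF11	neurodevelopment_gene	unknown	other	
KIF2A	neurodevelopment_gene	unknown	other	
KIF5C	neurodevelopment_gene	unknown	other	
LAMB1	neurodevelopment_gene	recessive	ecm	
LAMC3	neurodevelopment_gene	unknown	ecm	
MED17	neurodevelopment_gene	unknown	other	
MFSD2A	neurodevelopment_gene	unknown	other	
MPDZ	neurodevelopment_gene	unknown	other	
NDE1	neurodevelopment_gene	unknown	other	
NSDHL	neurodevelopment_gene	unknown	other	
OCLN	neurodevelopment_gene	unknown	other	
OPHN1	neurodevelopment_gene	x_linked	other	
PAFAH1B1	neurodevelopment_gene	unknown	other	
PCLO	neurodevelopment_gene	unknown	other	
PIK3R2	neurodevelopment_gene	unknown	signal_transduction	
PLEKHG2	neurodevelopment_gene	unknown	other	
PNKP	neurodevelopment_gene	unknown	other	
PPP1R15B	neurodevelopment_gene	unknown	other	
PTCH1	neurodevelopment_gene	unknown	other	
QARS	neurodevelopment_gene	unknown	other	
RELN	neurodevelopment_gene	dominant	ecm	
RTTN	neurodevelopment_gene	recessive	other	
SASS6	neurodevelopment_gene	unknown	other	
EPSECS	neurodevelopment_gene	unknown	other	
SLC12A6	neurodevelopment_gene	recessive	other	
SLC20A2	neurodevelopment_gene	unknown	other	
SNIP1	neurodevelopment_gene	unknown	other	
SPATA5	neurodevelopment_gene	unknown	other	
SRPX2	neurodevelopment_gene	x_linked	ecm	
STAMBP	neurodevelopment_gene	unknown	other	
STRADA	neurodevelopment_gene	unknown	mtor	
SYN1	neurodevelopment_gene	x_linked	other	
TRMT10A	neurodevelopment_gene	recessive	other	
TSC1	neurodevelopment_gene	dominant	mtor	
TSC2	neurodevelopment_gene	dominant	mtor	
TSEN15	neurodevelopment_gene	unknown	other	
TSEN2	neurodevelopment_gene	unknown	other	
TSEN54	neurodevelopment_gene	unknown	other	
TUBA1A	neurodevelopment_gene	unknown	other	
TUBA8	neurodevelopment_gene	recessive	other	
TUBB2A	neurodevelopment_gene	unknown	other	
TUBB2B	neurodevelopment_gene	unknown	other	
TUBB3	neurodevelopment_gene	unknown	other	
TUBG1	neurodevelopment_gene	unknown	other	
VPS53	neurodevelopment_gene	unknown	other	
WDR62	neurodevelopment_gene	unknown	other	
WDR73	neurodevelopment_gene	unknown	other	
XPR1	neurodevelopment_gene	unknown	other	
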