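# Affinity validation panel: wild-type/mutant peptide pairs measured by FP
# displacement against bait protein domains. K_D values in micromolar.
# kd limit codes: "" measured; "<" tighter than the bounding value given;
# "nb" no displacement within the titrated concentration range (kd NA).
# enrichment_score/p_value from the phage selection; NA = not determined.
# in_agreement_set marks the 24-pair agreement panel (importin-alpha ARM
# scored on the major pocket; minor-pocket rows kept as supplementary).
bait_id	pocket	protein_id	mutation	peptide	kd_wt	kd_wt_sem	kd_wt_limit	kd_mut	kd_mut_sem	kd_mut_limit	enrichment_score	p_value	in_agreement_set
ABL1_SH3	NA	TP53	P72R	64-YPRMPEAA(P/R)PVAPAPAAP-80	650	30		560	30		-6	6.3e-4	TRUE
CASK_kinase	NA	MAPT	R723W	717-YSGDTSP(R/W)HLSNVSST-731	NA	NA	nb	39	4		12	9.6e-7	TRUE
CASK_kinase	NA	FANCA	S4L	1-MSD(S/L)WVPNSASGQDPG-16	NA	NA	nb	15.0	0.7		6	6.3e-4	TRUE
CLTC_NTD	NA	BCL11A	C48F	44-DLLT(C/F)GQAQMNFPY-56	1100	380		361	43		12	9.6e-7	TRUE
CLTC_NTD	NA	MITF	Y265C	258-SGNLIDL(Y/C)GNQGLPY-271	191	27		206	13		-9.8	1.9e-7	TRUE
CREBBP_KIX	NA	KMT2A	L2854Q	2847-SDIMDFV(L/Q)KNTPSMQY-2861	380	30		340	10		-6.7	2.0e-4	TRUE
GABARAPL1_ATG8	NA	BUB1	S492F	486-DKDEWQ(S/F)LDQNEDAFE-501	5.5	0.7		0.3	NA	<	16	1.3e-8	TRUE
G3BP1_NTF2	NA	NSD1	L1797P	1793-EFPV(L/P)FFGSNDYLWTH-1808	12	2		49	1		-7.4	5.1e-5	TRUE
G3BP1_NTF2	NA	CTNNB1	S33F	27-QQSYLD(S/F)GIHSGATTT-42	NA	NA	nb	57	2		9	1.9e-5	TRUE
G3BP2_NTF2	NA	BCL11A	C48F	44-DLLT(C/F)GQAQMNFPY-56	NA	NA	nb	215	43		10	6.9e-6	TRUE
GGA1_VHS	NA	MYH9	D1424H	1419-QQELD(D/H)LLVDLDHQR-1433	101	3		306	3		-10	8.0e-6	TRUE
KEAP1_KELCH	NA	SQSTM1	P348L	343-SKEVD(P/L)STGELQSLY-356	0.9	0.1		23	3		-16	7.8e-8	TRUE
KPNA4_ARM	major	ABRAXAS1	R361Q	349-LDLDDRWQFKRS(R/Q)LLD-364	0.17	0.02		75	3		-6	4.5e-4	TRUE
KPNA4_ARM	major	CREBBP	K13E	5-LLDGPPNP(K/E)RAKLSS-19	0.000088	NA	<	60	20		-6	4.5e-4	TRUE
KPNA4_ARM	major	CDC45	R157C	152-EPSEK(R/C)TRLEEEIVEY-166	0.090	0.003		7	1		-7	1.7e-4	TRUE
KPNA4_ARM	major	ZNF526	K160T	152-PELWVAHR(K/T)AQHLSAT-167	135	3		NA	NA	nb	-6.4	4.8e-4	TRUE
KPNA4_ARM	minor	ABRAXAS1	R361Q	349-LDLDDRWQFKRS(R/Q)LLD-364	22	3		297	16		-6	4.5e-4	FALSE
KPNA4_ARM	minor	CREBBP	K13E	5-LLDGPPNP(K/E)RAKLSS-19	153	5		NA	NA	nb	-6	4.5e-4	FALSE
KPNA4_ARM	minor	CDC45	R157C	152-EPSEK(R/C)TRLEEEIVEY-166	91	11		545	70		-7	1.7e-4	FALSE
KPNA4_ARM	minor	ZNF526	K160T	152-PELWVAHR(K/T)AQHLSAT-167	69	1		395	10		-6.4	4.8e-4	FALSE
KPNA7_ARM	major	CDC45	R157C	152-EPSEK(R/C)TRLEEEIVEY-166	6.6	0.7		380	15		NA	NA	FALSE
MAP1LC3A_ATG8	NA	KRT1	L214P	209-QTKWE(L/P)LQQVDTSTRT-224	55	5		580	30		-6	3.9e-4	TRUE
MAP1LC3B_ATG8	NA	BUB1	S492F	486-DKDEWQ(S/F)LDQNEDAFE-501	7	1		1.6	0.1		12	7.4e-7	TRUE
MAP1LC3B_ATG8	NA	SQSTM1	P348L	334-GDDDWTHLSSKEVD(P/L)S-349	0.5	0.1		0.6	0.1		7.6	1.9e-4	TRUE
MAP1LC3B_ATG8	NA	BRCA2	T298I/V299L/V300R	292-EDEVYE(T/I)(V/L)(V/R)DTSEEDS-307	3.12	0.08		0.52	0.01		15	3.7e-8	TRUE
NEDD4_WW2	NA	SCNN1B	P616R	611-PIPGT(P/R)PPNYDSLRLQ-626	39	3		80	7		-12	7.4e-7	TRUE
NEDD4_WW2	NA	SCNN1B	P618R	611-PIPGTPP(P/R)NYDSLRLQ-626	39	3		603	73		-16	1.2e-8	TRUE
PPIA	NA	KMT2D	P2301S	2993-GASSPSYG(P/S)PNLGFVD-3308	177	20		1675	144		-8	5.1e-5	TRUE
USP7_MATH	NA	CHK2	Q51K	38-ISSSSTSTMPNSS(Q/K)SS-53	3.1	0.2		4.7	0.3		-6	3.6e-4	TRUE
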