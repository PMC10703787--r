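RBsig	synthetic placeholder for the Rb loss-of-function signature (E2F-target-like members; supply the published list to reproduce it)	CCNE1	CCNE2	E2F1	E2F2	MCM2	MCM3	MCM4	MCM5	MCM6	MCM7	CDC6	CDC20	CDT1	PCNA	RRM2	TYMS	TK1	CDC25A	CHAF1B	DHFR	POLE2	GINS1	GINS2	ORC1	ORC6	UHRF1	EZH2	FOXM1	MYBL2
IRPS	synthetic placeholder for the 35-gene interferon-related palbociclib-resistance signature	ISG15	IFI6	IFI27	IFI44	IFI44L	IFIT1	IFIT2	IFIT3	IFITM1	IFITM3	MX1	MX2	OAS1	OAS2	OAS3	OASL	STAT1	STAT2	IRF7	IRF9	BST2	RSAD2	USP18	HERC5	HERC6	SAMD9	SAMD9L	XAF1	EIF2AK2	DDX58	DDX60	IFIH1	PARP9	PARP12	GBP1
CCNE1	cyclin E1 single-gene marker	CCNE1
TILs	synthetic placeholder for the T-cell infiltration metagene	CD3D	CD3E	CD2	CD8A	CD52	GZMA	GZMB	GZMK	PRF1	CCL5	CXCL9	IL2RG
GEP	synthetic placeholder for the T-cell-inflamed gene expression profile aggregation=weighted_mean	CCL5	CD27	CD274	CD276	CD8A	CMKLR1	CXCL9	CXCR6	HLA-DQA1	HLA-DRB1	HLA-E	IDO1	LAG3	NKG7	PDCD1LG2	PSMB10	STAT1	TIGIT
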