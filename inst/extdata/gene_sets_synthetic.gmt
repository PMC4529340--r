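PAM50_like	synthetic intrinsic panel (45 genes)	ESR1	PGR	FOXA1	MLPH	NAT1	SLC39A6	MAPT	BAG1	GPR160	MDM2	MKI67	CCNB1	BIRC5	CDC20	UBE2C	RRM2	TYMS	CENPF	KIF2C	CCNE1	ERBB2	GRB7	FGFR4	TMEM45B	MMP11	KRT5	KRT14	KRT17	FOXC1	SFRP1	EGFR	CDH3	PHGDH	ACTR3B	MYC	BCL2	BLVRA	CDC6	ANLN	EXO1	NDC80	PTTG1	CEP55	UBE2T	MELK
claudin	claudin/E-cadherin epithelial panel	CLDN3	CLDN4	CLDN7	CDH1	OCLN
ECM_universe	synthetic ECM-related universe	SPARC	BGN	CDH11	FN1	LAMA4	MMP2	COL1A1	COL1A2	COL5A1	COL5A2	COL5A3	COL6A1	COL6A2	COL6A3	COL3A1	THBS2	POSTN	LUM	DCN	FBN1	CTSS	GZMK	MMP7	MMP9	SELL	SPOCK2	VCAM1	GZMA	GZMB	GZMH	GZMM	CTSC	CTSH	CTSW	CTSZ	ITGA4	ITGAL	ITGAX	ITGB2	ITGB7	ADAM7	ADAM28
ECM1_seed	immune protease/adhesion markers	CTSS	GZMK	MMP7	MMP9	SELL	SPOCK2	VCAM1
ECM3_seed	collagen/stromal signature	SPARC	BGN	CDH11	FN1	LAMA4	MMP2	COL1A1	COL1A2	COL5A1	COL5A2	COL5A3	COL6A1	COL6A2	COL6A3
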