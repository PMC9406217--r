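g2m	synthetic example: mitotic G2-G2/M phase genes	CDK1	CCNB1	PLK1	FOXM1	AURKB	BUB1	CDC25C	WEE1
kinome	synthetic example: protein kinase genes	CDK1	PLK1	AURKB	BUB1	WEE1	EGFR	SRC	MAPK1
matrisome	synthetic example: matrisome genes	FN1	COL6A1	TNC	LTBP1	MMP13	ANGPTL4	SEMA3C	C1QTNF1
adhesion	synthetic example: cell adhesion genes	ITGA1	ITGB1	CDH1	CXADR	FN1	TNC	LGALS9	UNC5B
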