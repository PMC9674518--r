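TDS	16 canonical thyroid differentiation genes (iodide handling and thyroid transcription factors)	DIO1	DIO2	DUOX1	DUOX2	FOXE1	GLIS3	NKX2-1	PAX8	SLC26A4	SLC5A5	SLC5A8	TG	THRA	THRB	TPO	TSHR
immune	editable default 66-gene immune cell surface marker and immune regulation set; replace with your curated list	PTPRC	CD2	CD3D	CD3E	CD3G	CD4	CD8A	CD8B	CD19	MS4A1	CD79A	CD79B	CD14	CD68	CD163	ITGAM	ITGAX	NCAM1	KLRD1	NKG7	GNLY	PRF1	GZMA	GZMB	GZMK	IFNG	TNF	IL2	IL2RA	IL2RB	IL2RG	IL7R	IL10	IL6	CXCL9	CXCL10	CXCL11	CCL2	CCL3	CCL4	CCL5	CCR5	CCR7	CXCR3	CXCR4	HLA-A	HLA-B	HLA-C	HLA-DRA	HLA-DRB1	HLA-DPA1	HLA-DQA1	B2M	TAP1	TAP2	PDCD1	CD274	PDCD1LG2	CTLA4	LAG3	HAVCR2	TIGIT	ICOS	CD28	CD40	CD40LG
stromal	editable default stromal / fibroblast enrichment set (ESTIMATE-style); replace with your curated list	FAP	ACTA2	PDGFRA	PDGFRB	COL1A1	COL1A2	COL3A1	COL5A1	COL6A1	COL6A2	COL6A3	FN1	VIM	THY1	DCN	LUM	POSTN	FBLN1	FBLN2	MMP2	SPARC	TAGLN	VCAN	CDH11	PDPN	ZEB1	TWIST1	SNAI2	S100A4	TNC
GEP	18-gene T-cell-inflamed gene expression profile	CCL5	CD27	CD274	CD276	CD8A	CMKLR1	CXCL9	CXCR6	HLA-DQA1	HLA-DRB1	HLA-E	IDO1	LAG3	NKG7	PDCD1LG2	PSMB10	STAT1	TIGIT
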