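B_cells_naive	synthetic_placeholder	CD79A	CD79B	MS4A1	CD19	TCL1A
B_cells_memory	synthetic_placeholder	CD27	IGHG1	IGHA1	MZB1	AIM2
Plasma_cells	synthetic_placeholder	IGHM	MZB1	SDC1	CD38	PRDM1
T_cells_CD8	synthetic_placeholder	CD8A	CD8B	GZMK	GZMA	PRF1
T_cells_CD4_naive	synthetic_placeholder	CD4	CCR7	SELL	TCF7	LEF1
T_cells_CD4_memory_resting	synthetic_placeholder	CD4	IL7R	CD40LG	ANXA1	S100A4
T_cells_CD4_memory_activated	synthetic_placeholder	CD4	CD69	ICOS	TNFRSF4	IL2RA
T_cells_follicular_helper	synthetic_placeholder	CXCR5	BCL6	ICOS	PDCD1	CD200
T_cells_regulatory	synthetic_placeholder	FOXP3	IL2RA	CTLA4	IKZF2	TNFRSF18
T_cells_gamma_delta	synthetic_placeholder	TRGC1	TRGC2	TRDC	KLRC1	NKG7
NK_cells_resting	synthetic_placeholder	KLRD1	KLRB1	NCR1	CD160	XCL1
NK_cells_activated	synthetic_placeholder	NKG7	GNLY	KLRK1	FCGR3A	PRF1
Monocytes	synthetic_placeholder	CD14	LYZ	S100A8	S100A9	FCN1
Macrophages_M0	synthetic_placeholder	CD68	MARCO	MSR1	CTSK	CHIT1
Macrophages_M1	synthetic_placeholder	CD80	CD86	IL1B	TNF	CXCL9
Macrophages_M2	synthetic_placeholder	CD163	MRC1	MSR1	CCL22	IL10
Dendritic_cells_resting	synthetic_placeholder	CD1C	FCER1A	CLEC10A	ITGAX	HLA-DQA1
Dendritic_cells_activated	synthetic_placeholder	CCR7	LAMP3	FSCN1	CD83	CCL19
Mast_cells_resting	synthetic_placeholder	TPSAB1	TPSB2	CPA3	MS4A2	HPGDS
Mast_cells_activated	synthetic_placeholder	KIT	CMA1	TPSD1	IL13	PTGS2
Eosinophils	synthetic_placeholder	SIGLEC8	CCR3	IL5RA	PRG2	EPX
Neutrophils	synthetic_placeholder	FCGR3B	CSF3R	S100A12	CXCR2	FPR1
MCP_T_cells	synthetic_placeholder	CD3D	CD3E	CD3G	CD28	TRAC
MCP_CD8_T_cells	synthetic_placeholder	CD8A	CD8B	GZMM	EOMES	KLRG1
MCP_Cytotoxic_lymphocytes	synthetic_placeholder	GZMA	GZMB	PRF1	KLRD1	GNLY
MCP_B_lineage	synthetic_placeholder	CD79A	CD79B	MS4A1	IGKC	PAX5
MCP_NK_cells	synthetic_placeholder	NCR1	KIR2DL3	KLRF1	NKG7	XCL2
MCP_Monocytic_lineage	synthetic_placeholder	CD14	CD68	CSF1R	ITGAM	LYZ
MCP_Myeloid_dendritic_cells	synthetic_placeholder	CD1C	CD1E	CLEC10A	FCER1A	WDFY4
MCP_Neutrophils	synthetic_placeholder	FCGR3B	CSF3R	CXCR2	S100A12	FPR1
MCP_Endothelial_cells	synthetic_placeholder	PECAM1	VWF	CDH5	CLDN5	KDR
MCP_Fibroblasts	synthetic_placeholder	COL1A1	COL1A2	COL3A1	DCN	FAP
Stromal_signature	synthetic_placeholder	COL1A1	COL3A1	DCN	FAP	ACTA2	PDGFRB	THY1	LUM
Immune_signature	synthetic_placeholder	PTPRC	CD3E	CD8A	CD19	NKG7	LYZ	CD14	CD79A
IFN_gamma	synthetic_placeholder	IFNG	STAT1	IDO1	CXCL9	CXCL10	HLA-DRA
CYT	synthetic_placeholder	GZMA	PRF1
TCR_signature	synthetic_placeholder	CD3D	CD3E	CD3G	TRAC	TRBC1	ZAP70
BCR_signature	synthetic_placeholder	CD79A	CD79B	IGHM	MS4A1	BLNK	BTK
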