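B cells	synthetic marker catalogue	CD19	MS4A1	CD79A	CD79B	BLK	TCL1A	BLNK	FCRL2
eosinophils	synthetic marker catalogue	IL5RA	CCR3	PRG2	EPX	RNASE2	RNASE3	SIGLEC8	CLC
macrophages	synthetic marker catalogue	CD68	CD163	MSR1	MRC1	CSF1R	MARCO	VSIG4	APOE
mast cells	synthetic marker catalogue	TPSAB1	TPSB2	CPA3	MS4A2	KIT	CMA1	HDC	SLC18A2
NK CD56bright cells	synthetic marker catalogue	NCAM1	XCL1	XCL2	KLRC1	GZMK	SELL	IL7R	CD44
NK CD56dim cells	synthetic marker catalogue	FCGR3A	KIR2DL3	KIR3DL1	GZMB	PRF1	SPON2	FGFBP2	CX3CR1
neutrophils	synthetic marker catalogue	FCGR3B	CSF3R	CXCR2	FPR1	S100A8	S100A9	ELANE	MPO
T helper cells	synthetic marker catalogue	CD4	CD28	ICOS	IL2RA	CD40LG	BATF	ANP32B	ASF1A
Tcm cells	synthetic marker catalogue	CCR7	SELL2	ATM	AQP3	CASP8	CDC14A	CLUAP1	TRAF1
Tem cells	synthetic marker catalogue	CCR2	EWSR1	FLI1	GDPD5	LTK	MEFV	NFATC4	TRA2A
Tfh cells	synthetic marker catalogue	CXCR5	BCL6	PDCD1	IL21	MAF	SH2D1A	TOX2	ICA1
aDCs	synthetic marker catalogue	CCL1	EBI3	IDO1	LAMP3	OAS3	INDO	CD83	CCR7B
iDCs	synthetic marker catalogue	CD1A	CD1B	CD1C	CD1E	F13A1	FCER1A	SYT17	PPFIBP2
activated CD8 T cells	synthetic marker catalogue	CD8A	CD8B	GZMA	GZMH	KLRG1	IFNG	NKG7	CCL5
gamma delta T cells	synthetic marker catalogue	TRGC1	TRGC2	TRDC	TARP	FEZ1	TUBB4A	CD160	KLRD1
Tregs	synthetic marker catalogue	FOXP3	IL2RB	CTLA4	IKZF2	TNFRSF18	TNFRSF4	CCR8	LRRC32
cytotoxic cells	synthetic marker catalogue	PRF1B	GZMM	KLRB1	KLRK1	KLRF1	CTSW	NKG2D	ZAP70
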