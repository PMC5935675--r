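STAT3_SIG_A	synthetic placeholder STAT3-induced signature (not the published list)	SOCS3	MYC	JUNB	BCL3	OSMR	IL6R	MCL1	PIM1	CCND1	ICAM1
STAT3_SIG_B	synthetic placeholder STAT3-induced signature (not the published list)	SOCS3	EGFR	STAT3	BCL6	FOS	IER3	SERPINB3	MUC1	CD274	HIF1A
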