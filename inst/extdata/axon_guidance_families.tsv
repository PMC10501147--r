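gene	family	confidence
SLIT1	SLIT	high
SLIT2	SLIT	high
SLIT3	SLIT	high
ROBO1	ROBO	high
ROBO2	ROBO	high
ROBO3	ROBO	high
ROBO4	ROBO	uncertain
EFNA1	EFN	high
EFNA2	EFN	high
EFNA3	EFN	high
EFNA4	EFN	high
EFNA5	EFN	high
EFNB1	EFN	high
EFNB2	EFN	high
EFNB3	EFN	high
EPHA1	EPH	high
EPHA2	EPH	high
EPHA3	EPH	high
EPHA4	EPH	high
EPHA5	EPH	high
EPHA6	EPH	high
EPHA7	EPH	high
EPHA8	EPH	high
EPHB1	EPH	high
EPHB2	EPH	high
EPHB3	EPH	high
EPHB4	EPH	high
EPHB6	EPH	uncertain
SEMA3A	SEMA	high
SEMA3B	SEMA	high
SEMA3C	SEMA	high
SEMA3D	SEMA	high
SEMA3E	SEMA	high
SEMA3F	SEMA	high
SEMA3G	SEMA	high
SEMA4A	SEMA	high
SEMA4B	SEMA	high
SEMA4C	SEMA	high
SEMA4D	SEMA	high
SEMA4F	SEMA	high
SEMA4G	SEMA	high
SEMA5A	SEMA	high
SEMA5B	SEMA	high
SEMA6A	SEMA	high
SEMA6B	SEMA	high
SEMA6C	SEMA	high
SEMA6D	SEMA	high
SEMA7A	SEMA	high
NRP1	NRP	high
NRP2	NRP	high
PLXNA1	PLXN	high
PLXNA2	PLXN	high
PLXNA3	PLXN	high
PLXNA4	PLXN	high
PLXNB1	PLXN	high
PLXNB2	PLXN	high
PLXNB3	PLXN	high
PLXNC1	PLXN	high
PLXND1	PLXN	high
LAMA1	LAM	high
LAMA2	LAM	high
LAMA3	LAM	high
LAMA4	LAM	high
LAMA5	LAM	high
LAMB1	LAM	high
LAMB2	LAM	high
LAMB3	LAM	high
LAMB4	LAM	uncertain
LAMC1	LAM	high
LAMC2	LAM	high
LAMC3	LAM	high
FLRT1	FLRT	high
FLRT2	FLRT	high
FLRT3	FLRT	high
UNC5A	UNC5	high
UNC5B	UNC5	high
UNC5C	UNC5	high
UNC5D	UNC5	high
NTN1	NTN	high
NTN3	NTN	uncertain
NTN4	NTN	high
DCC	DCC	high
NEO1	DCC	uncertain
WNT3	WNT	high
WNT5A	WNT	high
WNT7B	WNT	uncertain
CXCL12	CXCL	high
CXCR4	CXCR	high
EDNRA	EDNR	high
BOC	BOC	high
TRIO	TRIO	high
RAC2	RAC	high
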