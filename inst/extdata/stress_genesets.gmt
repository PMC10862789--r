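ISR	curated ATF4-driven integrated stress response targets	ATF4	ATF3	DDIT3	CHAC1	ASNS	PSAT1	PHGDH	SESN2	TRIB3	PPP1R15A	GADD45A	SLC7A11	VEGFA
UPR	curated ER unfolded protein response targets (ATF6 + IRE1/XBP1s arms)	HSPA5	HSP90B1	HERPUD1	CALR	PDIA4	HYOU1	SEL1L	CRELD2	SDF2L1	MANF	XBP1	DNAJB9	SEC24D	SSR1	DNAJC3	EDEM1	SEC61A1	SERP1	PDIA6	TMED2
ATF6	ATF6-arm UPR targets	HSPA5	HSP90B1	HERPUD1	CALR	PDIA4	HYOU1	SEL1L	CRELD2	SDF2L1	MANF
IRE1_XBP1s	IRE1/XBP1s-arm UPR targets	XBP1	DNAJB9	SEC24D	SSR1	DNAJC3	EDEM1	SEC61A1	SERP1	PDIA6	TMED2
HSR	curated HSF1-driven heat shock response targets	HSPA1A	HSPA1B	HSPB1	HSPH1	DNAJB1	DNAJA1	BAG3	HSP90AA1	CHORDC1	FKBP4	AHSA1	CACYBP
OSR	curated NRF2-driven oxidative stress response targets	NQO1	HMOX1	GCLC	GCLM	TXNRD1	GSR	FTL	FTH1	ME1	SRXN1	PRDX1	OSGIN1
CONTROL	stable-expression control panel	GAPDH	ACTB	TUBB	RPL19	RPS18	PGK1	PPIA	B2M	HPRT1	TBP	GUSB	YWHAZ	SDHA	UBC	RPLP0	EEF1A1	POLR2A	PUM1	TFRC
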