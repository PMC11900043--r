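feature	gene_id	chromosome	start	end	strand	is_essential
gene	YCR001W	chrIII	115000	115900	+	FALSE
gene	CDC10	chrIII	116300	117280	-	FALSE
gene	MRPL32	chrIII	117800	118360	+	FALSE
gene	YCP4	chrIII	118700	119440	-	FALSE
gene	CIT2	chrIII	120000	121380	-	FALSE
gene	YCR006C	chrIII	121800	122300	-	FALSE
gene	YCR007C	chrIII	122700	123200	-	FALSE
centromere	CEN3	chrIII	114385	114501	+	FALSE
telomeric_repeat	TEL03R	chrIII	315000	316000	+	FALSE
gene	KGD1	chrIX	120000	123042	+	FALSE
gene	AYR1	chrIX	123500	124390	+	FALSE
gene	SIM1	chrIX	125000	126430	+	FALSE
gene	POG1	chrIX	127000	128050	+	FALSE
gene	QDR2	chrIX	128600	130240	+	FALSE
gene	QDR1	chrIX	130800	132440	+	FALSE
gene	RPI1	chrIX	133000	134230	+	FALSE
centromere	CEN9	chrIX	355600	355720	+	FALSE
gene	SLS1	chrXII	420000	421680	-	FALSE
gene	YLR140W	chrXII	422200	422700	+	FALSE
gene	RRN5	chrXII	423200	424280	+	TRUE
gene	PUT1	chrXII	424900	426280	+	FALSE
gene	DPH6	chrXII	426900	428870	+	FALSE
gene	ACF2	chrXII	429400	431690	-	FALSE
gene	RMP1	chrXII	432200	432900	+	FALSE
centromere	CEN12	chrXII	151450	151570	+	FALSE
gene	YPL114W	chrXVI	333000	334000	+	FALSE
gene	YPL113C	chrXVI	334600	335900	-	FALSE
gene	PEX25	chrXVI	336400	337580	-	FALSE
gene	CAR1	chrXVI	338000	339000	-	FALSE
gene	GDE1	chrXVI	339600	343260	-	FALSE
gene	YPL109C	chrXVI	343900	345600	-	FALSE
gene	YPL108W	chrXVI	346200	347000	+	FALSE
gene	EAF3	chrXVI	608000	609200	-	FALSE
gene	YME1	chrXVI	609800	612000	+	FALSE
gene	CCL1	chrXVI	612500	613700	-	TRUE
gene	ATH1	chrXVI	614300	617900	+	FALSE
gene	YPR027C	chrXVI	618400	619200	-	FALSE
gene	YOP1	chrXVI	619700	620240	+	FALSE
gene	APL4	chrXVI	620800	623300	-	FALSE
gene	SKI3	chrXVI	915000	919300	+	FALSE
gene	RPC82	chrXVI	919900	921860	-	FALSE
gene	QCR2	chrXVI	922400	923500	+	FALSE
gene	AQY1	chrXVI	924000	924920	+	FALSE
gene	HPA1	chrXVI	925500	926670	-	FALSE
gene	OPT2	chrXVI	927200	929900	-	FALSE
gene	YPR195C	chrXVI	930400	931000	-	FALSE
centromere	CEN16	chrXVI	555950	556070	+	FALSE
telomeric_repeat	TEL16R	chrXVI	943000	948000	+	FALSE
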