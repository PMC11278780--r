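strain	mtAC	mtBA	ppzA-A1	ppzA-T1	ppzA-C	ppzA-A2	ppzA-M	ppzA-T2	ppzA-R	ppzA-dR	dmaW	easF	easC	easE	easD	easA	easG	cloA	lpsB	lpsA	easH	lpsC	easO	easP	idtG	idtB	idtM	idtC	idtS	idtP	idtQ	idtF	idtK	idtE	idtJ	lolC	lolF	lolD	lolT	lolU	lolA	lolO	lolP	lolE	lolN	lolM
ADX8	+	-	+	+	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	+	+	+	+	+	+	+	-	-	+	-	-	-	-	-	-	-	-	-	-
ADX12	+	-	+	+	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	+	+	+	+	+	+	+	-	-	+	-	-	-	-	-	-	-	-	-	-
ADX9	+	-	+	+	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	+	+	+	+	+	+	+	-	-	+	-	-	-	-	-	-	-	-	-	-
AD16	+	-	+	+	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	+	+	+	+	+	+	+	-	-	+	-	-	-	-	-	-	-	-	-	-
FC1	+	-	+	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	+	+	+	-	+	+	+	-	-	+	-	-	-	-	-	-	-	-	-	-
FC4	+	-	+	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	+	+	+	-	+	+	+	-	-	+	-	-	-	-	-	-	-	-	-	-
LE6	+	-	+	+	+	+	+	+	+	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-
LE1	+	-	+	+	+	+	+	+	+	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-
LE3	+	-	+	+	+	+	+	+	+	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-
LE7	+	-	+	+	+	+	+	+	+	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-
GA7	+	-	+	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	+	+	+	-	+	+	+	-	-	+	-	-	-	-	-	-	-	-	-	-
GA2	+	-	+	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	+	+	+	-	+	+	+	-	-	+	-	-	-	-	-	-	-	-	-	-
AD3	+	-	+	+	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	+	+	+	+	+	+	+	-	-	+	-	-	-	-	-	-	-	-	-	-
AD5	+	-	+	+	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	+	+	+	+	+	+	+	-	-	+	-	-	-	-	-	-	-	-	-	-
GA4	+	-	+	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	+	+	+	-	+	+	+	-	-	+	-	-	-	-	-	-	-	-	-	-
KE1	+	-	+	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	+	+	+	+	+	+	+	-	-	+	-	-	-	-	-	-	-	-	-	-
KEM1	+	-	+	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	+	+	+	+	+	+	+	-	-	+	-	-	-	-	-	-	-	-	-	-
KEM3	+	-	+	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	+	+	+	+	+	+	+	-	-	+	-	-	-	-	-	-	-	-	-	-
KEM4	+	-	+	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	+	+	+	+	+	+	+	-	-	+	-	-	-	-	-	-	-	-	-	-
LB1	+	-	+	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+	+	+	+	-	-	-	+	+	+	+	+	+	+	+	+	-	-	+	-	-	-	-	-	-	-	-	-	-
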