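gene	label_sites	position	strand	exon	codon_from	codon_to	codon_position	aa_from	aa_to	level
nad1	4	99048	+	exon 1	CUA	UUA	1	L	L	18
nad1	4	99201	+	exon 1	CCG	UCG	1	P	S	88
nad1	4	344481	+	exon 3	CCC	CCU	3	P	P	33
nad1	4	726995	-	exon 5	AAC	AAU	3	F	N	63
nad2	5	297295	-	exon 2	CCA	CUA	2	P	L	92
nad2	5	463531	+	exon 4	UUC	UUU	3	F	F	18
nad2	5	463653	+	exon 4	CCG	CUG	2	P	L	81
nad2	5	465022	+	exon 5	UCC	UUC	2	S	F	70
nad2	5	465030	+	exon 5	CUC	UUC	1	L	F	64
nad3	1	20810	-		CCA	CUA	2	P	L	92
nad4	3	578975	+	exon 3	CUA	UUA	1	L	L	36
nad4	3	579324	+	exon 3	CCA	CUA	2	P	L	94
nad4	3	581798	+	exon 4	ACC	ACU	3	T	T	93
nad5	5	260779	-	exon 2	GCC	GCU	3	A	A	29
nad5	5	260950	-	exon 2	AUC	AUU	3	I	I	20
nad5	5	261311	-	exon 2	GCC	GUC	2	A	V	75
nad5	5	261673	-	exon 2	ACC	ACU	3	T	T	25
nad5	5	261677	-	exon 2	CCG	CUG	2	P	L	92
nad6	2	300266	-		CCA	CUA	2	P	L	93
nad6	2	300273	-		CCC	UCC	1	P	S	90
nad7	13	711488	+	exon 1	AAC	AAU	3	N	N	13
nad7	13	712855	+	exon 2	UCU	UUU	2	S	F	70
nad7	13	713691	+	exon 3	CGU	UGU	1	R	C	100
nad7	13	713819	+	exon 3	GUC	GUU	3	V	V	24
nad7	13	713906	+	exon 3	UCC	UCU	3	S	S	12
nad7	13	714114	+	exon 3	CUU	UUU	1	L	F	91
nad7	13	715347	+	exon 4	CCU	CUU	2	P	L	72
nad7	13	715366	+	exon 4	UCC	UCU	3	S	S	61
nad7	13	715453	+	exon 4	CCC	CCU	3	P	P	88
nad7	13	715506	+	exon 4	UCU	UUU	2	S	F	85
nad7	13	715522	+	exon 4	CAC	CAU	3	H	H	72
nad7	13	715527	+	exon 4	CCA	CUA	2	P	L	98
nad7	13	715569	+	exon 4	UCU	UUU	2	S	F	100
nad9	3	497201	+		UCU	UUU	2	S	F	73
nad9	3	497282	+		CCA	CUA	2	P	L	47
nad9	3	497708	+		UCU	UUU	2	S	F	78
cob	2	779528	+		UCU	UUU	2	S	F	92
cob	2	779794	+		CUA	UUA	1	L	L	86
cox1	2	321763	+	exon 1	ACC	ACU	3	T	T	89
cox1	2	323181	+	exon 2	CUG	UUG	1	L	L	96
cox2	1	514300	+		CUA	UUA	1	L	L	84
cox3	1	558125	+		UUC	UUU	3	F	F	67
atp4	2	285091	+		CCC	CUC	2	P	L	87
atp4	2	285114	+		CCG	UCG	1	P	S	95
atp6	2	810361	-		UCC	UCU	3	S	S	48
atp6	2	810993	-		CGU	UGU	1	R	C	64
atp8	1	556640	+		UGC	UGU	3	C	C	84
ccmFc	3	834747	+	exon 1	CAU	UAU	1	H	Y	63
ccmFc	3	834901	+	exon 1	CCA	CUA	2	P	L	77
ccmFc	3	836320	+	exon 2	CUA	UUA	1	L	L	32
ccmFn	1	488236	-		ACC	AUC	2	T	I	61
rpl5	4	22103	-		CCG	UCG	1	P	S	16
rpl5	4	22105	-		CCU	CUU	2	P	L	77
rpl5	4	22173	-		AUC	AUU	3	I	I	13
rpl5	4	22389	-		UCC	UCU	3	S	S	31
rpl10	3	611859	+		ACC	ACU	3	T	T	35
rpl10	3	611934	+		CGG	UGG	1	R	W	41
rpl10	3	612084	+		UAC	UAU	3	Y	Y	40
matR	7	102277	+		UCC	UCU	3	S	S	96
matR	7	103757	+		CGC	UCG	1	R	S	16
matR	7	103771	+		UAC	UAU	3	Y	Y	75
rps3	4	263919	-	exon 2	CCG	CUG	2	P	L	97
rps3	4	263864	-	exon 2	UCC	UCU	3	S	S	48
rps3	4	264252	-	exon 2	CCA	CUA	2	P	L	15
rps3	4	264811	-	exon 2	CGA	UGA	1	R	Stop	85
rps4	1	267470	-		UCC	UCU	3	S	S	56
rps12	1	20376	-		CCC	CCU	3	P	P	11
rps14	2	21929	-		UCC	UCU	3	S	S	21
rps14	2	21974	-		CCC	CCU	3	P	P	17
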