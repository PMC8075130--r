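##fileformat=VCFv4.2
##contig=<ID=chrM,length=600>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AF,Number=1,Type=Float,Description="Alt allele fraction">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	F001	F002	F003	F004	F005	F006	NF001	NF002	NF003	NF004	NF005	NF006	NF007	NF008	NF009	NF010
chrM	22	.	T	G	.	PASS	.	GT:AF	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	1:1	0:.	0:.	0:.
chrM	27	.	C	G	.	PASS	.	GT:AF	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	1:1	0:.	0:.	0:.
chrM	37	.	G	C	.	PASS	.	GT:AF	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	40	.	T	C	.	PASS	.	GT:AF	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	72	.	G	C	.	PASS	.	GT:AF	0:.	0:.	0:.	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	83	.	G	C	.	PASS	.	GT:AF	0:.	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	86	.	A	G	.	PASS	.	GT:AF	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.
chrM	108	.	A	G	.	PASS	.	GT:AF	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.
chrM	117	.	T	G	.	PASS	.	GT:AF	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	1:1	0:.
chrM	122	.	T	C	.	PASS	.	GT:AF	0:.	0:.	1:1	0:.	0:.	1:1	0:.	1:1	1:1	1:1	1:1	0:.	1:1	1:1	1:1	1:1
chrM	154	.	A	G	.	PASS	.	GT:AF	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	160	.	G	C	.	PASS	.	GT:AF	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	161	.	C	A	.	PASS	.	GT:AF	1:1	1:1	0:.	1:1	1:1	0:.	1:1	0:.	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.
chrM	195	.	A	G	.	PASS	.	GT:AF	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	197	.	T	G	.	PASS	.	GT:AF	1:1	1:1	0:.	1:1	1:1	0:.	1:1	0:.	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.
chrM	201	.	T	G	.	PASS	.	GT:AF	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	213	.	G	T	.	PASS	.	GT:AF	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	1:1	0:.
chrM	239	.	T	A	.	PASS	.	GT:AF	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.
chrM	252	.	C	A	.	PASS	.	GT:AF	0:.	0:.	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	262	.	A	C	.	PASS	.	GT:AF	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0/1:0.5	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	286	.	T	G	.	PASS	.	GT:AF	0:.	0:.	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	296	.	G	C	.	PASS	.	GT:AF	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	328	.	T	G	.	PASS	.	GT:AF	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.
chrM	334	.	T	A	.	PASS	.	GT:AF	1:1	1:1	0:.	0:.	1:1	0:.	1:1	0:.	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.
chrM	351	.	T	C	.	PASS	.	GT:AF	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	387	.	T	C	.	PASS	.	GT:AF	1:1	1:1	0:.	0:.	1:1	0:.	1:1	0:.	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.
chrM	400	.	G	A	.	PASS	.	GT:AF	1:1	0:.	0:.	0:.	0:.	0:.	1:1	0:.	0:.	1:1	0:.	1:1	1:1	1:1	1:1	0:.
chrM	415	.	C	A	.	PASS	.	GT:AF	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	445	.	A	G	.	PASS	.	GT:AF	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	1:1	0:.
chrM	451	.	C	T	.	PASS	.	GT:AF	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	465	.	C	G	.	PASS	.	GT:AF	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	498	.	T	G	.	PASS	.	GT:AF	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	511	.	C	T	.	PASS	.	GT:AF	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.
chrM	528	.	G	C	.	PASS	.	GT:AF	0:.	0:.	1:1	0:.	0:.	1:1	0:.	1:1	1:1	1:1	1:1	0:.	1:1	1:1	1:1	1:1
chrM	555	.	T	G	.	PASS	.	GT:AF	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	570	.	T	A	.	PASS	.	GT:AF	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	578	.	T	A	.	PASS	.	GT:AF	0:.	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
chrM	593	.	A	T	.	PASS	.	GT:AF	0:.	0:.	0:.	1:1	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.	0:.
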