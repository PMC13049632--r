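##fileformat=VCFv4.2
##reference=GRCh38
##INFO=<ID=AF,Number=A,Type=Float,Description="gnomAD v4.1.0 allele frequency; absent when the variant is not observed in the population database">
##INFO=<ID=CADD,Number=A,Type=Float,Description="CADD Phred score">
##INFO=<ID=PHYLOP,Number=A,Type=Float,Description="PhyloP100 conservation score">
##INFO=<ID=INH,Number=1,Type=String,Description="Reported inheritance (pass-through)">
##contig=<ID=chr9>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr9	134164501	.	G	C	.	PASS	CADD=19;PHYLOP=3.98;INH=paternal
chr9	134164522	.	C	T	.	PASS	AF=0.00001313;CADD=19;PHYLOP=4.72;INH=maternal
chr9	134164522	.	C	T	.	PASS	AF=0.00001313;CADD=19;PHYLOP=4.72;INH=paternal
chr9	134164529	.	A	C	.	PASS	CADD=18;PHYLOP=7.12;INH=paternal
chr9	134164535	.	G	A	.	PASS	AF=0.00000658;CADD=21;PHYLOP=7.62;INH=maternal
chr9	134164537	.	G	A	.	PASS	AF=0.0000789;CADD=21;PHYLOP=9.55;INH=maternal
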