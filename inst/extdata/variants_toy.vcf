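##fileformat=VCFv4.2
##INFO=<ID=POPAF,Number=A,Type=Float,Description="Population allele frequency">
##INFO=<ID=DBSNP_MAF,Number=A,Type=Float,Description="dbSNP minor allele frequency">
##INFO=<ID=TOPMED_MAF,Number=A,Type=Float,Description="TOPMed minor allele frequency">
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	TUMOR
chr1	100	.	A	G	.	PASS	POPAF=0.001	AD:DP	90,10:100
chr1	200	.	C	T	.	PASS	GENE=JAK3	AD:DP	70,30:100
chr2	300	.	G	A	.	PASS	DBSNP_MAF=0.2	AD:DP	45,5:50
chr2	400	.	T	C	.	PASS	GENE=ATM	AD:DP	194,6:200
chrX	500	.	G	C	.	PASS	TOPMED_MAF=0.01	AD:DP	5,5:10
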