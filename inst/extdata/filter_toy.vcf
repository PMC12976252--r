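##fileformat=VCFv4.2
##INFO=<ID=POPAF,Number=A,Type=Float,Description="Population allele frequency">
##INFO=<ID=DBSNP_MAF,Number=A,Type=Float,Description="dbSNP minor allele frequency">
##INFO=<ID=TOPMED_MAF,Number=A,Type=Float,Description="TOPMed minor allele frequency">
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	TUMOR
chr1	1000	.	A	G	.	PASS	.	AD:DP	57,3:60
chr1	2000	.	C	T	.	PASS	POPAF=0.01;DBSNP_MAF=0.05;TOPMED_MAF=0.05	AD:DP	300,200:500
chr2	3000	.	G	A	.	PASS	POPAF=0.001	AD:DP	970,30:1000
chr2	4000	.	T	C	.	PASS	POPAF=0.02	AD:DP	8,2:10
chr11	5000	.	G	C	.	PASS	GENE=ATM	AD:DP	40,40:80
chr17	6000	.	A	T	.	PASS	GENE=STAT5B	AD:DP	5,5:10
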