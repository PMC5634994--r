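##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	T1_R1	T1_R2
chr7	55259515	.	T	G	.	PASS	.	GT:AD	0/1:60,40	0/1:70,30
chr12	25398284	.	C	T,A	.	PASS	.	GT:AD	0/1:80,20,5	0/0:95,0,0
chr17	7578406	.	C	T	.	PASS	.	GT:AD	0/1:50,50	0/1:55,45
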