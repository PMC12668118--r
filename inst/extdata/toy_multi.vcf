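##fileformat=VCFv4.2
##contig=<ID=chr1>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2
chr1	100	rs1	A	G	.	PASS	.	GT	0/0	0/1
chr1	200	rs2	C	T,G	.	PASS	.	GT	0/1	0/2
chr1	300	rs3	G	A	.	PASS	.	GT	1/1	0/0
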