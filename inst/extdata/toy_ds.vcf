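##fileformat=VCFv4.2
##contig=<ID=chr1>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2
chr1	100	rs1	A	G	.	PASS	.	GT:DS	0/0:0.12	0/1:1.31
chr1	200	rs2	C	T	.	PASS	.	GT:DS	1/1:1.88	0/0:0.02
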