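##fileformat=VCFv4.2
##contig=<ID=chr6,length=40>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	SAMPLE
chr6	14	snp_1	C	T	.	PASS	.	GT	0|1
chr6	19	snp_2	C	G	.	PASS	.	GT	1|0
chr6	25	snp_3	G	T	.	PASS	.	GT	1|0
chr6	33	snp_4	A	C	.	PASS	.	GT	0|1
chr6	38	snp_5	A	G	.	PASS	.	GT	1|0
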