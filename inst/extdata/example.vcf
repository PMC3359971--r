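##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	ind1	ind2	ind3
5	74656539	rs_demo1	C	T	.	PASS	.	GT	0/0	0/1	1/1
15	58683366	rs_demo2	A	G	.	PASS	.	GT	0/1	./.	0/0
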