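##fileformat=VCFv4.2
##source=hybridsex_toy_fixture
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3	s4
LG1	1000	t1	A	T	.	PASS	.	GT	0/0	0/1	1/1	0/0
LG1	2000	t2	C	G	.	PASS	.	GT	0/1	0/1	0/0	1/1
LG2	1500	t3	G	A	.	PASS	.	GT	1/1	0/0	0/1	0/1
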