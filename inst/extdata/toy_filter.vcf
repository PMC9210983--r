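##fileformat=VCFv4.2
##contig=<ID=chr1,length=2000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3	s4	s5	s6	s7	s8
chr1	100	.	A	T	50	PASS	.	GT:DP:GQ	0/0:20:99	0/1:20:99	0/0:22:99	0/1:18:99	1/1:20:99	0/1:20:99	0/0:21:99	0/1:19:99
chr1	200	.	G	C	50	PASS	.	GT:DP:GQ	0/1:20:99	0/0:20:99	0/1:20:99	0/0:20:99	0/1:20:99	1/1:20:99	0/1:20:99	0/0:20:99
chr1	300	.	A	T,G	50	PASS	.	GT:DP:GQ	0/1:20:99	0/2:20:99	0/0:20:99	0/1:20:99	0/0:20:99	0/2:20:99	0/1:20:99	0/0:20:99
chr1	400	.	ATG	A	50	PASS	.	GT:DP:GQ	0/0:20:99	0/1:20:99	0/0:20:99	0/0:20:99	0/1:20:99	0/0:20:99	0/0:20:99	0/1:20:99
chr1	405	.	C	G	50	PASS	.	GT:DP:GQ	0/0:20:99	0/1:20:99	0/1:20:99	0/0:20:99	0/1:20:99	0/0:20:99	0/1:20:99	0/0:20:99
chr1	406	.	T	A	50	PASS	.	GT:DP:GQ	0/1:20:99	0/0:20:99	0/0:20:99	0/1:20:99	0/0:20:99	0/1:20:99	0/0:20:99	0/1:20:99
chr1	500	.	G	A	50	PASS	.	GT:DP:GQ	1/1:20:99	0/1:20:99	0/0:20:99	0/1:20:99	0/0:20:99	0/1:20:99	1/1:20:99	0/0:20:99
chr1	1000	.	C	T	50	PASS	.	GT:DP:GQ	0/1:3:99	0/0:3:99	0/1:3:99	0/1:20:99	0/0:20:99	0/1:20:99	0/0:20:99	0/1:20:99
chr1	1100	.	A	C	50	PASS	.	GT:DP:GQ	0/0:20:99	0/1:20:99	0/1:20:99	0/0:20:99	1/1:20:99	0/1:20:99	0/0:20:99	0/1:20:99
chr1	1200	.	T	G	50	PASS	.	GT:DP:GQ	0/1:20:99	0/0:20:99	0/1:20:99	0/1:20:99	0/0:20:99	0/1:20:99	1/1:20:99	0/0:20:99
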