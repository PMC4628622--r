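##fileformat=VCFv4.2
##source=cosegr
##contig=<ID=11>
##contig=<ID=18>
##contig=<ID=19>
##contig=<ID=3>
##contig=<ID=7>
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence class">
##INFO=<ID=MAF,Number=1,Type=Float,Description="Population minor allele frequency">
##INFO=<ID=COHORTDB,Number=1,Type=String,Description="Present in in-house cohort database">
##INFO=<ID=BRAINEXP,Number=1,Type=String,Description="Gene has validated brain expression">
##INFO=<ID=MERGED,Number=1,Type=String,Description="Keys of merged adjacent substitutions">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AO,Number=A,Type=Integer,Description="Alternate allele read count">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	IV:1	IV:5	IV:7	IV:9	V:6	V:7	V:8	III:2	IV:6	IV:11
11	61560000	.	C	T	.	PASS	.	GT:AO	0/1:27	0/1:29	0/1:31	0/1:33	0/1:35	0/1:37	0/1:39	0/0:.	0/0:.	0/0:.
18	59450000	.	G	A	.	PASS	.	GT:AO	0/1:35	0/1:37	0/1:39	0/1:41	0/1:43	0/1:45	0/1:47	0/0:.	0/0:.	0/0:.
19	32840000	.	C	G	.	PASS	.	GT:AO	0/1:29	0/1:31	0/1:33	0/1:35	0/1:37	0/1:39	0/1:41	0/0:.	0/0:.	0/0:.
3	134264558	.	G	T	.	PASS	.	GT:AO	0/1:33	0/1:35	0/1:37	0/1:39	0/1:41	0/1:43	0/1:45	0/0:.	0/0:.	0/0:.
3	134264559	.	A	T	.	PASS	.	GT:AO	0/1:30	0/1:32	0/1:34	0/1:36	0/1:38	0/1:40	0/1:42	0/0:.	0/0:.	0/0:.
7	926250	.	T	G	.	PASS	.	GT:AO	0/1:24	0/1:26	0/1:28	0/1:30	0/1:32	0/1:34	0/1:36	0/0:.	0/0:.	0/0:.
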