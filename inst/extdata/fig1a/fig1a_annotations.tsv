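chrom	pos	ref	alt	gene	consequence	pop_maf	in_cohort_db	brain_expressed	gerp	polyphen2	sift
3	134264558	GA	TT	CEP63	non_synonymous	1e-04	FALSE	TRUE	5.53	1	0
7	926250	T	G	GET4	non_synonymous		FALSE	TRUE			
11	61560000	C	T	INTS5	non_synonymous		FALSE	TRUE			
18	59450000	G	A	RNF152	non_synonymous		FALSE	TRUE			
19	32840000	C	G	ZNF507	non_synonymous		FALSE	TRUE			
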