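##fileformat=VCFv4.2
##source=synthetic_example
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr2L	150	.	A	C	60	PASS	.
chr2L	420	.	G	T	55	PASS	.
chr2L	1210	.	C	A	58	PASS	.
chr2L	1677	.	T	G	52	PASS	.
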