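chr2L	0	1000	geneA
chr2L	1000	2000	geneB
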