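gene	role	label	sequence
UBA	forward	UBA1	CTGGGAATAGGCCTTCTACAT
UBA	forward	UBA4	GGCATCTGCAGTAACCCACT
UBA	reverse	UBA_R	TCCAGATACTTCTTCAGCCAC
DAA	forward	DAA	TGCTGGCAGGTGTATGCAGAA
DAA	reverse	DAA_R	GGTGAAATCAGCGTTGGGGT
DAB	forward	DAB1	ATGTCGATGTCTATCTTCTG
DAB	forward	DAB2	TTCTGCGTTTCCCTGACCC
DAB	reverse	DAB_R	GTACCAGTCCCCGTTAGCCAG
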